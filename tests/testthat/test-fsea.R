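test_that("residuals are orthogonal to every covariate", {
  set.seed(41)
  n <- 60
  md <- data.frame(sample_id = paste0("s", 1:n),
                   srs2_tscore = stats::rnorm(n, 50, 9),
                   a = stats::rnorm(n), b = stats::rbinom(n, 1, 0.4),
                   c = stats::rnorm(n))
  r <- residualize(md, c("a", "b", "c"))
  for (cv in c("a", "b", "c"))
    expect_lt(abs(sum(r * md[[cv]])), 1e-8)
  # score an exact linear function of covariates -> all-zero residuals
  md2 <- md
  md2$srs2_tscore <- 3 + 2 * md$a - md$b
  expect_equal(unname(residualize(md2, c("a", "b", "c"))), rep(0, n),
               tolerance = 1e-10)
  # covariates orthogonal to the (centered) score leave it unchanged
  md3 <- md
  md3$a <- stats::residuals(stats::lm(a ~ srs2_tscore, md))
  r3 <- residualize(md3, "a")
  expect_equal(unname(r3),
               md3$srs2_tscore - mean(md3$srs2_tscore), tolerance = 1e-8)
})

test_that("correlations match the covariance-formula oracle and filter", {
  set.seed(43)
  n <- 50
  m <- matrix(stats::rlnorm(n * 20), n,
              dimnames = list(paste0("s", 1:n), paste0("U", 1:20)))
  # family proportional to the measure -> r = 1
  measure <- stats::setNames(stats::rnorm(n, 50, 8), rownames(m))
  m[, 1] <- 3 * measure
  # family in only 3 subjects -> excluded at min_subjects = 4
  m[, 2] <- 0
  m[1:3, 2] <- 1
  tab <- abundance_table(m, "genefamily")
  cv <- correlate_features(tab, measure, min_subjects = 4)
  expect_equal(cv$r[cv$feature == "U1"], 1, tolerance = 1e-12)
  expect_false("U2" %in% cv$feature)
  expect_equal(attr(cv, "n_low_prevalence"), 1L)
  # literal covariance / variance formula oracle
  for (f in sample(cv$feature, 8)) {
    x <- m[, f]
    r_oracle <- sum((x - mean(x)) * (measure - mean(measure))) /
      sqrt(sum((x - mean(x))^2) * sum((measure - mean(measure))^2))
    expect_equal(cv$r[cv$feature == f], unname(r_oracle),
                 tolerance = 1e-12)
  }
  expect_error(correlate_features(abundance_table(m[1:2, , drop = FALSE],
                                                  "genefamily"),
                                  measure[1:2]), "fewer than 3")
})

test_that("Mann-Whitney enrichment reproduces the exact hand case", {
  cv <- structure(data.frame(feature = c("i1", "i2", "o1", "o2"),
                             r = c(0.5, 0.3, 0.1, 0.2),
                             n = 10, prevalence = 10),
                  class = c("correlation_vector", "data.frame"))
  res <- mwu_enrichment(cv, c("i1", "i2"), set_name = "demo")
  expect_equal(res$U, 4)
  expect_equal(res$p, 2 / choose(4, 2), tolerance = 1e-12)
  expect_equal(res$med, 0.4)
  # complement identity: U + U' = n_in * n_out
  res_sw <- mwu_enrichment(cv, c("o1", "o2"), set_name = "swap")
  expect_equal(res$U + res_sw$U, 2 * 2)
})

test_that("exact Mann-Whitney p matches exhaustive enumeration", {
  set.seed(47)
  for (n1 in 1:4) for (n2 in 1:4) {
    x <- stats::rnorm(n1)
    y <- stats::rnorm(n2)
    got <- gutsea:::mwu_test(x, y)
    oracle <- mwu_enumerate(x, y)
    expect_equal(got$U, oracle$U)
    expect_equal(got$p, oracle$p, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney agrees with wilcox.test and its normal branch", {
  set.seed(53)
  x <- stats::rnorm(30, 0.3)
  y <- stats::rnorm(40)
  got <- gutsea:::mwu_test(x, y)
  wt <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
  expect_equal(got$U, unname(wt$statistic))
  expect_equal(got$p, wt$p.value, tolerance = 1e-10)
  # tie-corrected normal approximation within 0.02 of exact on tie-free data
  big_x <- stats::rnorm(25, 0.2)
  big_y <- stats::rnorm(25)
  exact_p <- stats::wilcox.test(big_x, big_y, exact = TRUE,
                                correct = FALSE)$p.value
  normal_p <- gutsea:::mwu_test(c(big_x, 0), c(big_y, 0))  # tie forces normal
  expect_lt(abs(stats::wilcox.test(c(big_x, 0), c(big_y, 0), exact = FALSE,
                                   correct = FALSE)$p.value - normal_p$p),
            1e-10)
  approx_only <- gutsea:::mwu_test(rep(big_x, 5), rep(big_y, 5))
  expect_true(approx_only$p > 0 && approx_only$p <= 1)
  expect_lt(abs(gutsea:::mwu_test_normal_p(big_x, big_y) - exact_p), 0.02)
})

test_that("symmetric null gives U = n1 n2 / 2 and p = 1", {
  vals <- c(0.11, 0.32, 0.53, 0.74)
  cv <- structure(data.frame(feature = paste0("f", 1:8),
                             r = c(vals, vals), n = 9, prevalence = 9),
                  class = c("correlation_vector", "data.frame"))
  res <- mwu_enrichment(cv, paste0("f", 1:4))
  expect_equal(res$U, 4 * 4 / 2)
  expect_equal(res$p, 1)
})

test_that("run_fsea flags the planted set and respects the q threshold", {
  cfg <- small_config(101, n_subjects = c(A = 80), windows = "early",
                      n_genefamilies = 400, n_sets = 6,
                      set_size = c(30, 30),
                      planted_sets = c(synthetic_set_01 = 0.4),
                      planted_species = numeric(),
                      planted_metabolites = numeric())
  ch <- generate_cohort(cfg)
  md <- ch$metadata
  res <- run_fsea(ch$genefamilies, md, ch$catalog,
                  covariates = c("gestational_age", "sex"),
                  measures = "score")
  expect_equal(res$set[1], "synthetic_set_01")
  expect_true(res$significant[1])
  expect_identical(res$significant, !is.na(res$q) & res$q < 0.1)
  expect_true(all(diff(res$q) >= 0))
  # in-set families never appear in the out-of-set pool
  expect_equal(res$n_in[1] + res$n_out[1],
               nrow(correlate_features(
                 ch$genefamilies,
                 stats::setNames(md$srs2_tscore, md$sample_id))))
})

test_that("run_fsea computes both measures and empty sets are untestable", {
  cfg <- small_config(103, n_subjects = c(A = 50), windows = "early")
  ch <- generate_cohort(cfg)
  cat2 <- ch$catalog
  cat2$sets$ghost <- character()
  res <- run_fsea(ch$genefamilies, ch$metadata, cat2,
                  covariates = c("gestational_age", "sex"))
  expect_setequal(unique(res$measure), c("score", "residual"))
  ghost <- res[res$set == "ghost" & res$measure == "score", ]
  expect_true(ghost$untestable)
  expect_true(is.na(ghost$p))
})

test_that("planted in-set correlation recovers monotonically with delta", {
  deltas <- c(0, 0.05, 0.1, 0.2)
  meds <- vapply(deltas, function(d) {
    reps <- vapply(1:8, function(r) {
      cfg <- small_config(200 + r, n_subjects = c(A = 100),
                          windows = "early", n_genefamilies = 300,
                          n_sets = 4, set_size = c(40, 40),
                          planted_sets = c(synthetic_set_01 = d),
                          planted_species = numeric(),
                          planted_metabolites = numeric(),
                          covariate_effects = numeric())
      ch <- generate_cohort(cfg)
      res <- run_fsea(ch$genefamilies, ch$metadata, ch$catalog,
                      measures = "score")
      res$med[res$set == "synthetic_set_01"]
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_false(is.unsorted(meds))
  expect_lt(abs(meds[1]), 0.05)
})

test_that("taxon contributions rank shares that sum to one", {
  strat <- data.frame(
    feature_id = c("U1", "U1", "U2"),
    taxon = c("Escherichia_coli", "Anaerostipes_hadrus",
              "Escherichia_coli"),
    sample_id = "s1",
    value = c(4, 4, 2))
  m <- matrix(c(8, 2), 1, 2, dimnames = list("s1", c("U1", "U2")))
  tab <- abundance_table(m, "genefamily", stratified = strat)
  tc <- taxon_contribution(tab, c("U1", "U2"))
  expect_equal(tc$share, c(0.6, 0.4))
  expect_equal(tc$taxon[1], "Escherichia_coli")
  expect_equal(sum(tc$share), 1, tolerance = 1e-9)
  # single contributing taxon -> share 1
  tc1 <- taxon_contribution(tab, "U2")
  expect_equal(tc1$share, 1)
  expect_warning(taxon_contribution(tab, "U404"), "no stratified rows")
})
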