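test_that("config validation enforces the mandatory seed and bounds", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(seed = 1, sparsity = c(taxon = 1.2,
                                                        genefamily = 0.3)))
  expect_error(simulation_config(seed = 1,
                                 planted_sets = c(synthetic_set_01 = 1.5)))
  expect_error(simulation_config(seed = 1, n_genefamilies = 10,
                                 set_size = c(20, 60)), "set size")
})

test_that("metadata marginals match the configured moments", {
  cfg <- simulation_config(seed = 11, n_subjects = c(A = 200),
                           windows = "early",
                           score_intercept = c(A = 50),
                           score_noise_sd = c(A = 10),
                           covariate_effects = numeric(),
                           missingness = numeric())
  md <- generate_metadata(cfg)
  expect_equal(nrow(md), 200)
  expect_lt(abs(mean(md$srs2_tscore) - 50), 3 * 10 / sqrt(200))
  expect_gt(stats::sd(md$srs2_tscore), 8)
  expect_lt(stats::sd(md$srs2_tscore), 12)
  # missingness rate 0 -> no masked entries
  covs <- intersect(default_covariate_schema()$name, names(md))
  expect_false(anyNA(md[, covs]))
})

test_that("metadata generation is deterministic and applies MCAR masks", {
  cfg <- small_config(13)
  m1 <- generate_metadata(cfg)
  m2 <- generate_metadata(cfg)
  expect_identical(m1, m2)
  # masked covariates acted on the score before masking (truth retained)
  truth <- attr(m1, "truth")
  expect_false(anyNA(truth$breastfeeding))
  # both windows share the subject's covariates and score
  early <- m1[m1$sample_age_window == "early", ]
  late <- m1[m1$sample_age_window == "late", ]
  expect_equal(early$srs2_tscore[match(late$subject_id, early$subject_id)],
               late$srs2_tscore)
})

test_that("taxonomic table is compositional with the configured sparsity", {
  cfg <- small_config(17, n_subjects = c(A = 100), windows = "early",
                      n_species = 100,
                      sparsity = c(taxon = 0.9, genefamily = 0.3),
                      planted_species = numeric())
  md <- generate_metadata(cfg)
  tab <- generate_taxonomic(cfg, md)
  sums <- rowSums(tab$values)
  expect_true(all(abs(sums - 1) < 1e-9 | sums == 0))
  zero_frac <- mean(tab$values == 0)
  expect_gt(zero_frac, 0.85)
  expect_lt(zero_frac, 0.95)
})

test_that("null species/score correlations are centered at zero", {
  cfg <- small_config(19, n_subjects = c(A = 200), windows = "early",
                      n_species = 50, planted_species = numeric(),
                      covariate_effects = numeric())
  ch <- generate_cohort(cfg)
  r <- suppressWarnings(
    stats::cor(ch$taxonomic$values, ch$metadata$srs2_tscore))
  r <- r[is.finite(r)]
  expect_lt(abs(mean(r)), 0.03)
  # mean |r| consistent with a null at n = 200 (E|r| ~ sqrt(2/(pi n)))
  expect_lt(mean(abs(r)), 3 * sqrt(1 / 200))
})

test_that("gene-family construction hits the planted log-scale correlation", {
  cfg <- small_config(23, n_subjects = c(A = 150), windows = "early",
                      n_genefamilies = 200, n_sets = 2,
                      set_size = c(50, 50),
                      sparsity = c(taxon = 0.6, genefamily = 0),
                      planted_sets = c(synthetic_set_01 = 0.9),
                      planted_species = numeric(),
                      planted_metabolites = numeric())
  ch <- generate_cohort(cfg)
  memb <- ch$catalog$sets$synthetic_set_01
  logv <- log(ch$genefamilies$values[, memb])
  rs <- apply(logv, 2, stats::cor, y = ch$metadata$srs2_tscore)
  expect_lt(abs(stats::median(rs) - 0.9), 0.1)
})

test_that("stratified contributions conserve the community total", {
  cfg <- small_config(29, n_subjects = c(A = 30), windows = "early")
  ch <- generate_cohort(cfg)
  st <- ch$genefamilies$stratified
  expect_false(is.null(st))
  key <- paste(st$sample_id, st$feature_id)
  first <- !duplicated(key)
  sums <- rowsum(st$value, factor(key, levels = key[first]))
  parent <- ch$genefamilies$values[cbind(st$sample_id[first],
                                         st$feature_id[first])]
  expect_equal(unname(sums[, 1]), unname(parent), tolerance = 1e-9)
})

test_that("metabolites are positive and recover the planted per-doubling effect", {
  cfg <- simulation_config(seed = 31, n_subjects = c(A = 500),
                           windows = "early", n_species = 20,
                           n_genefamilies = 20, n_sets = 2,
                           set_size = c(3, 5),
                           covariate_effects = numeric(),
                           planted_species = numeric(),
                           planted_sets = numeric(),
                           planted_metabolites = c(butyrate = 0.86),
                           confound_breastfeeding_metabolite = 0,
                           score_noise_sd = c(A = 4))
  ch <- generate_cohort(cfg)
  expect_true(all(ch$metabolites > 0))
  fit <- metabolite_regression(ch$metabolites, ch$metadata)
  b <- fit$estimate[fit$metabolite == "butyrate"]
  expect_gt(b, 0.66)
  expect_lt(b, 1.06)
})

test_that("confounding through breastfeeding attenuates on adjustment", {
  atten <- vapply(1:30, function(s) {
    cfg <- simulation_config(seed = 400 + s, n_subjects = c(A = 150),
                             windows = "early", n_species = 10,
                             n_genefamilies = 10, n_sets = 2,
                             set_size = c(2, 3),
                             covariate_effects = c(breastfeeding = -4),
                             planted_species = numeric(),
                             planted_sets = numeric(),
                             planted_metabolites = c(butyrate = 0.5),
                             confound_breastfeeding_metabolite = 2,
                             missingness = numeric(),
                             score_noise_sd = c(A = 3))
    ch <- generate_cohort(cfg)
    un <- metabolite_regression(ch$metabolites, ch$metadata)
    ad <- metabolite_regression(ch$metabolites, ch$metadata,
                                covariates = "breastfeeding",
                                adjusted = TRUE)
    abs(ad$estimate[ad$metabolite == "butyrate"]) <
      abs(un$estimate[un$metabolite == "butyrate"])
  }, logical(1))
  expect_gte(mean(atten), 0.8)
})

test_that("identical config and seed regenerate the cohort exactly", {
  cfg <- small_config(37)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$taxonomic$values, c2$taxonomic$values)
  expect_identical(c1$genefamilies$values, c2$genefamilies$values)
  expect_identical(c1$metabolites, c2$metabolites)
  c3 <- generate_cohort(small_config(38))
  expect_false(identical(c1$taxonomic$values, c3$taxonomic$values))
})

test_that("written cohort round-trips through the profile readers", {
  cfg <- small_config(41, n_subjects = c(A = 10), windows = "early",
                      n_species = 8, n_genefamilies = 12, n_sets = 2,
                      set_size = c(2, 3))
  ch <- generate_cohort(cfg)
  dir <- tempfile()
  write_cohort(ch, dir)
  tax <- read_taxonomic_profiles(file.path(dir, "taxonomic.tsv"))
  expect_equal(tax$values[rownames(ch$taxonomic$values),
                          colnames(ch$taxonomic$values)],
               ch$taxonomic$values, tolerance = 1e-6)
  md <- read_metadata(file.path(dir, "metadata.csv"))
  expect_equal(md$srs2_tscore, ch$metadata$srs2_tscore, tolerance = 1e-6)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$config$seed, 41)
})
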