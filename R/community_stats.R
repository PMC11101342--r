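#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarities
#' \eqn{d(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} between all samples
#' of an abundance table (computed via [vegan::vegdist()]).  A pair of
#' all-zero samples has an undefined ratio; it is defined as 0 with a
#' warning.
#'
#' @param table an `abundance_table` (or samples x features matrix).
#' @return A [stats::dist] object labeled with sample ids.
#' @export
bray_curtis <- function(table) {
  m <- if (inherits(table, "abundance_table")) table$values else table
  if (any(m < 0)) stop("negative abundance values")
  d <- withCallingHandlers(
    vegan::vegdist(m, method = "bray"),
    warning = function(w) {
      if (grepl("empty rows|missing values in results",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (anyNA(d)) {
    warning("distance between all-zero samples defined as 0")
    d[is.na(d)] <- 0
  }
  d
}

#' Alpha diversity of a single sample
#'
#' Shannon index \eqn{H = -\sum p_i \ln p_i} (natural log; zero proportions
#' contribute nothing) or inverse Simpson \eqn{1 / \sum p_i^2}, computed on
#' the vector rescaled to proportions.
#'
#' @param sample non-negative abundance vector.
#' @param index `"shannon"` or `"inverse_simpson"`.
#' @return A single number; `NA` with a warning for an all-zero vector.
#' @export
alpha_diversity <- function(sample, index = c("shannon", "inverse_simpson")) {
  index <- match.arg(index)
  if (any(sample < 0)) stop("negative abundance values")
  if (sum(sample) == 0) {
    warning("all-zero sample: diversity undefined")
    return(NA_real_)
  }
  vegan_index <- c(shannon = "shannon", inverse_simpson = "invsimpson")[index]
  as.numeric(vegan::diversity(sample / sum(sample), index = vegan_index))
}

#' Per-sample alpha diversity of an abundance table
#' @param table an `abundance_table`.
#' @param index `"shannon"` or `"inverse_simpson"`.
#' @return Named numeric vector, one value per sample.
#' @export
alpha_diversity_table <- function(table,
                                  index = c("shannon", "inverse_simpson")) {
  index <- match.arg(index)
  vapply(rownames(table$values), function(s)
    suppressWarnings(alpha_diversity(table$values[s, ], index)), numeric(1))
}

#' PERMANOVA with marginal sums of squares
#'
#' Permutational multivariate ANOVA on a distance matrix, testing each term
#' of the design marginally (given all other terms), as `adonis2` with
#' `by = "margin"` does.  The squared distances are Gower-centered into the
#' inner-product matrix G; a term's marginal SS is
#' `trace(H_full G) - trace(H_reduced G)` where the H are hat matrices of the
#' full design and of the design with that term removed.  Significance comes
#' from free permutation of metadata rows (implemented by conjugate
#' permutation of G, which is equivalent and fast), with the add-one
#' estimator `p = (1 + #[F* >= F]) / (1 + n_permutations)`.
#'
#' @param dist a [stats::dist] object or symmetric matrix.
#' @param metadata data.frame with one row per sample, aligned to `dist`
#'   labels when present.
#' @param terms character vector of metadata column names entering the
#'   design; every listed term is tested marginally.
#' @param n_permutations number of permutations (>= 99; default 9999).
#' @param seed integer seed for the permutation stream.
#' @return A data.frame of class `permanova_result`: one row per term plus
#'   `Residual` and `Total`, with columns `term`, `df`, `SS`, `R2`, `F`, `p`.
#' @export
permanova_marginal <- function(dist, metadata, terms, n_permutations = 9999,
                               seed = 1) {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (!is.null(rownames(D)) && all(rownames(D) %in% rownames(metadata)))
    metadata <- metadata[rownames(D), , drop = FALSE]
  if (nrow(metadata) != n) stop("metadata rows do not match distance matrix")
  if (n_permutations < 99) stop("n_permutations must be >= 99")
  mf <- metadata[, terms, drop = FALSE]
  if (anyNA(mf))
    stop("incomplete covariate rows; impute or drop upstream")
  for (j in seq_along(mf))
    if (is.character(mf[[j]])) mf[[j]] <- factor(mf[[j]])

  X <- stats::model.matrix(~ ., data = mf)
  asg <- attr(X, "assign")
  rank_full <- qr(X)$rank
  if (rank_full < ncol(X)) {
    piv <- qr(X)$pivot
    bad <- colnames(X)[piv[(rank_full + 1):ncol(X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  if (n <= ncol(X)) stop("fewer samples than design parameters")

  G <- gower_center(D)
  tr_G <- sum(diag(G))
  Hf <- hat_matrix(X)
  term_idx <- seq_along(terms)
  Hr <- lapply(term_idx, function(k)
    hat_matrix(X[, asg != k, drop = FALSE]))
  df_term <- vapply(term_idx, function(k) sum(asg == k), numeric(1))
  df_resid <- n - rank_full

  stat <- function(Gp) {
    trHf <- sum(Hf * Gp)
    ss_res <- sum(diag(Gp)) - trHf
    ss <- vapply(seq_along(Hr), function(k) trHf - sum(Hr[[k]] * Gp),
                 numeric(1))
    (ss / df_term) / (ss_res / df_resid)
  }
  F_obs <- stat(G)
  trHf <- sum(Hf * G)
  ss_res <- tr_G - trHf
  ss_obs <- (F_obs * df_term) * (ss_res / df_resid)

  set.seed(seed)
  exceed <- numeric(length(terms))
  for (b in seq_len(n_permutations)) {
    p <- sample.int(n)
    exceed <- exceed + (stat(G[p, p]) >= F_obs)
  }
  pval <- (1 + exceed) / (1 + n_permutations)

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df_term, df_resid, n - 1),
    SS = c(ss_obs, ss_res, tr_G),
    R2 = c(ss_obs, ss_res, tr_G) / tr_G,
    F = c(F_obs, NA, NA),
    p = c(pval, NA, NA),
    stringsAsFactors = FALSE)
  attr(out, "n_permutations") <- n_permutations
  attr(out, "seed") <- seed
  class(out) <- c("permanova_result", "data.frame")
  out
}

gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  rm <- rowMeans(A)
  sweep(sweep(A, 1, rm), 2, rm) + mean(A)
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Linear regression of SRS-2 score on standardized diversity
#'
#' Ordinary least squares of the score on z-standardized alpha diversity
#' plus covariates; the diversity coefficient is therefore the score
#' difference per standard-deviation increase in diversity.
#'
#' @param diversity per-sample diversity values, aligned to `metadata` rows.
#' @param metadata data.frame with `srs2_tscore` and covariate columns.
#' @param covariates character vector of adjustment columns (may be empty).
#' @param ci `"normal"` (+/- 1.96 SE, the default) or `"t"`.
#' @return A `regression_result` data.frame (see [ols_regression()]); the
#'   diversity term is named `"diversity_sd"`.
#' @export
diversity_regression <- function(diversity, metadata,
                                 covariates = character(),
                                 ci = c("normal", "t")) {
  ci <- match.arg(ci)
  if (stats::sd(diversity, na.rm = TRUE) == 0)
    stop("zero-variance diversity")
  df <- data.frame(srs2_tscore = metadata$srs2_tscore,
                   diversity_sd = as.numeric(scale(diversity)))
  for (cv in covariates) df[[cv]] <- metadata[[cv]]
  ols_regression(df, outcome = "srs2_tscore", ci = ci)
}

#' Ordinary least squares with tidy output
#'
#' Fits `outcome ~ .` on a complete-case data.frame and returns one row per
#' coefficient with estimate, SE, confidence bounds and p-value.  Rank
#' deficiency (aliased coefficients) is an error rather than a silent drop.
#'
#' @param data data.frame of outcome and predictors (character columns are
#'   treated as factors).
#' @param outcome name of the outcome column.
#' @param ci `"normal"` for +/- 1.96 SE bounds, `"t"` for t-quantile bounds.
#' @return A data.frame of class `regression_result` with columns `term`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
ols_regression <- function(data, outcome, ci = c("normal", "t")) {
  ci <- match.arg(ci)
  data <- data[stats::complete.cases(data), , drop = FALSE]
  for (j in seq_along(data))
    if (is.character(data[[j]])) data[[j]] <- factor(data[[j]])
  fit <- stats::lm(stats::reformulate(".", response = outcome), data = data)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; aliased term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  s <- summary(fit)$coefficients
  crit <- if (ci == "normal") stats::qnorm(0.975)
          else stats::qt(0.975, df = fit$df.residual)
  out <- data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
                    ci_low = s[, 1] - crit * s[, 2],
                    ci_high = s[, 1] + crit * s[, 2],
                    p = s[, 4], n = nrow(data),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "model") <- deparse(stats::formula(fit))
  attr(out, "fit") <- fit
  class(out) <- c("regression_result", "data.frame")
  out
}
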