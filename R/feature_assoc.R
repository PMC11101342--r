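#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment
#' (`q_(i) = min_{j >= i} m p_(j) / j`, capped at 1), computed through
#' [stats::p.adjust()] after input validation.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Table-level pseudocount
#'
#' Half the smallest nonzero value of the table, the standard additive
#' constant for log-transforming relative abundances.
#'
#' @param table an `abundance_table` or numeric matrix/vector.
#' @return A single positive number.
#' @export
default_pseudocount <- function(table) {
  m <- if (inherits(table, "abundance_table")) table$values else table
  half_min_nonzero(m)
}

#' Chained-equation imputation of missing covariates
#'
#' A compact chained-equations imputer: continuous covariates are imputed by
#' predictive mean matching (OLS on all other covariates, donor pool of the
#' `k` observed rows with closest predictions), binary covariates by
#' logistic-score matching (same donor scheme on the fitted logistic score).
#' Each of the `m` completed copies runs on its own seeded stream;
#' `n_iterations` full sweeps are made per copy.  Observed cells are never
#' altered.
#'
#' @param metadata data.frame with missing covariate cells as `NA`.
#' @param covariates character vector of covariate columns to impute/use as
#'   predictors; defaults to the schema covariates present in `metadata`.
#' @param m number of completed copies (default 20).
#' @param n_iterations chained-equation sweeps per copy (default 10).
#' @param seed integer seed.
#' @param k donor-pool size (default 5).
#' @param binary optional character vector naming binary covariates;
#'   defaults to columns whose observed values are all 0/1.
#' @return An object of class `imputed_set`: list with `copies` (list of `m`
#'   completed data.frames), `m`, `n_iterations`, `seed`.
#' @export
impute_covariates <- function(metadata, covariates = NULL, m = 20,
                              n_iterations = 10, seed = 1, k = 5,
                              binary = NULL) {
  if (is.null(covariates))
    covariates <- intersect(default_covariate_schema()$name, names(metadata))
  X <- metadata[, covariates, drop = FALSE]
  all_missing <- vapply(X, function(v) all(is.na(v)), logical(1))
  if (any(all_missing))
    stop("covariate(s) 100% missing: ",
         paste(covariates[all_missing], collapse = ", "))
  if (is.null(binary))
    binary <- covariates[vapply(X, function(v)
      all(stats::na.omit(v) %in% c(0, 1)), logical(1))]
  need <- covariates[vapply(X, anyNA, logical(1))]
  copies <- vector("list", m)
  for (copy in seq_len(m)) {
    set.seed(seed + copy)
    imp <- X
    for (cv in need) {
      miss <- is.na(imp[[cv]])
      imp[[cv]][miss] <- sample(imp[[cv]][!miss], sum(miss), replace = TRUE)
    }
    if (length(need)) for (it in seq_len(n_iterations)) {
      for (cv in need) {
        miss <- is.na(X[[cv]])
        imp[[cv]] <- impute_one(imp, cv, miss, k,
                                binary = cv %in% binary)
      }
    }
    out <- metadata
    out[, covariates] <- imp
    copies[[copy]] <- out
  }
  structure(list(copies = copies, m = m, n_iterations = n_iterations,
                 seed = seed), class = "imputed_set")
}

impute_one <- function(imp, cv, miss, k, binary) {
  others <- setdiff(names(imp), cv)
  dat <- imp[, others, drop = FALSE]
  y <- imp[[cv]]
  y[miss] <- NA
  fitdat <- data.frame(.y = y, dat)
  pred <- if (binary) {
    fit <- suppressWarnings(stats::glm(.y ~ ., data = fitdat,
                                       family = stats::binomial()))
    if (!fit$converged) {
      warning("logistic imputation model for '", cv,
              "' did not converge; drawing from observed frequency")
      p_obs <- mean(y[!miss])
      out <- imp[[cv]]
      out[miss] <- stats::rbinom(sum(miss), 1, p_obs)
      return(out)
    }
    stats::predict(fit, newdata = fitdat, type = "link")
  } else {
    fit <- stats::lm(.y ~ ., data = fitdat)
    stats::predict(fit, newdata = fitdat)
  }
  out <- imp[[cv]]
  obs_idx <- which(!miss)
  for (i in which(miss)) {
    d <- abs(pred[obs_idx] - pred[i])
    donors <- obs_idx[order(d)[seq_len(min(k, length(obs_idx)))]]
    out[i] <- y[sample(donors, 1)]
  }
  out
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled coefficient = mean of the per-imputation estimates; total variance
#' = mean within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance.  Confidence bounds and p-values use the
#' normal approximation.
#'
#' @param estimates m x p matrix (or list of vectors) of coefficient
#'   estimates.
#' @param variances m x p matrix (or list) of squared standard errors.
#' @return A `regression_result` data.frame with one row per coefficient and
#'   extra columns `within_var`, `between_var`, `total_var`.
#' @export
pool_rubin <- function(estimates, variances) {
  est <- if (is.list(estimates)) do.call(rbind, estimates) else
    rbind(estimates)
  vr <- if (is.list(variances)) do.call(rbind, variances) else
    rbind(variances)
  if (!all(dim(est) == dim(vr)))
    stop("estimates and variances have mismatched dimensions")
  m <- nrow(est)
  beta <- colMeans(est)
  W <- colMeans(vr)
  B <- if (m > 1) apply(est, 2, stats::var) else rep(0, ncol(est))
  total <- W + (1 + 1 / m) * B
  se <- sqrt(total)
  z <- beta / se
  crit <- stats::qnorm(0.975)
  out <- data.frame(
    term = colnames(est) %||% paste0("term", seq_along(beta)),
    estimate = beta, se = se,
    ci_low = beta - crit * se, ci_high = beta + crit * se,
    p = 2 * stats::pnorm(-abs(z)), n = NA_integer_,
    within_var = W, between_var = B, total_var = total,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "m") <- m
  class(out) <- c("regression_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-feature association screen
#'
#' MaAsLin2-style screen: for each feature passing the prevalence filter,
#' ordinary least squares of `log2(relative abundance + pseudocount)` on the
#' SRS-2 score plus covariates, with the abundance as the outcome.  The
#' score coefficient is reported per feature with Benjamini-Hochberg
#' q-values across retained features.
#'
#' @param table a normalized `abundance_table`.
#' @param metadata complete-case (or imputed) metadata aligned to the
#'   table's samples.
#' @param covariates character vector of adjustment columns.
#' @param min_prevalence minimum fraction of samples with nonzero abundance
#'   (default 0.1).
#' @param pseudocount additive constant before log2; default
#'   [default_pseudocount()] of the table.
#' @return A data.frame of class `feature_screen_result` with columns
#'   `feature`, `estimate`, `se`, `p`, `q`, `prevalence`; the number of
#'   features dropped by the filter is in the `"n_dropped"` attribute.
#' @export
feature_screen <- function(table, metadata, covariates = character(),
                           min_prevalence = 0.1, pseudocount = NULL) {
  m <- table$values[metadata$sample_id, , drop = FALSE]
  pc <- pseudocount %||% default_pseudocount(m)
  prev <- colMeans(m > 0)
  keep <- prev >= min_prevalence
  n_dropped <- sum(!keep)
  if (!any(keep)) {
    warning("no features pass the prevalence filter")
    out <- data.frame(feature = character(), estimate = numeric(),
                      se = numeric(), p = numeric(), q = numeric(),
                      prevalence = numeric(), stringsAsFactors = FALSE)
  } else {
    covdat <- metadata[, covariates, drop = FALSE]
    res <- lapply(colnames(m)[keep], function(f) {
      df <- data.frame(.ab = log2(m[, f] + pc),
                       srs2_tscore = metadata$srs2_tscore, covdat)
      fit <- ols_regression(df, outcome = ".ab")
      fit[fit$term == "srs2_tscore", c("estimate", "se", "p")]
    })
    res <- do.call(rbind, res)
    out <- data.frame(feature = colnames(m)[keep], res,
                      q = bh_fdr(res$p), prevalence = prev[keep],
                      row.names = NULL, stringsAsFactors = FALSE)
  }
  attr(out, "n_dropped") <- n_dropped
  attr(out, "pseudocount") <- pc
  attr(out, "transformation") <- "log2(relative abundance + pseudocount)"
  class(out) <- c("feature_screen_result", "data.frame")
  out
}

#' Score-on-abundance regression in per-doubling units
#'
#' The reverse model of the screen: ordinary least squares of the SRS-2
#' score on `log2(relative abundance + pseudocount)` plus covariates.  The
#' abundance coefficient is the score difference per doubling of relative
#' abundance.
#'
#' @param feature abundance vector aligned to `metadata` rows.
#' @param metadata data.frame with `srs2_tscore` and covariates.
#' @param covariates character vector of adjustment columns.
#' @param pseudocount additive constant before log2 (default half the
#'   smallest nonzero value of `feature`).
#' @param ci `"normal"` or `"t"` confidence bounds.
#' @return A `regression_result`; the abundance term is `"log2_abundance"`.
#' @export
reverse_regression <- function(feature, metadata, covariates = character(),
                               pseudocount = NULL, ci = c("normal", "t")) {
  ci <- match.arg(ci)
  if (stats::sd(feature) == 0) stop("constant feature")
  pc <- pseudocount %||% half_min_nonzero(feature)
  df <- data.frame(srs2_tscore = metadata$srs2_tscore,
                   log2_abundance = log2(feature + pc),
                   metadata[, covariates, drop = FALSE])
  ols_regression(df, outcome = "srs2_tscore", ci = ci)
}

#' Sex-interaction model for a single feature
#'
#' Adds a sex x log2-abundance product term to the reverse regression and
#' tests its coefficient; also fits the model separately within each sex.
#'
#' @inheritParams reverse_regression
#' @return A list with `p_interaction`, `interaction_estimate`, and
#'   per-sex `regression_result`s (`male`, `female`).
#' @export
interaction_model <- function(feature, metadata, covariates = character(),
                              pseudocount = NULL) {
  sexes <- table(metadata$sex)
  if (!all(c("male", "female") %in% names(sexes)))
    stop("both sexes must be present")
  if (any(sexes[c("male", "female")] < 10))
    stop("need >= 10 samples per sex")
  pc <- pseudocount %||% half_min_nonzero(feature)
  la <- log2(feature + pc)
  male <- as.numeric(metadata$sex == "male")
  df <- data.frame(srs2_tscore = metadata$srs2_tscore,
                   log2_abundance = la, sex_male = male,
                   log2_abundance_x_sex = la * male,
                   metadata[, setdiff(covariates, "sex"), drop = FALSE])
  full <- ols_regression(df, outcome = "srs2_tscore")
  strat <- lapply(c(male = "male", female = "female"), function(sx) {
    sel <- metadata$sex == sx
    reverse_regression(feature[sel], metadata[sel, , drop = FALSE],
                       setdiff(covariates, "sex"), pseudocount = pc)
  })
  ia <- full[full$term == "log2_abundance_x_sex", ]
  list(p_interaction = ia$p, interaction_estimate = ia$estimate,
       male = strat$male, female = strat$female, full = full)
}
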