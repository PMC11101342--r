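#' Fit a cross-cohort score-prediction model
#'
#' Trains a linear model of SRS-2 scores on log2-transformed shared-feature
#' abundances plus covariates in one cohort, for transfer prediction in
#' another.  A feature is "shared" when its prevalence (fraction of samples
#' with nonzero abundance) reaches `min_shared_prevalence` in the training
#' table and, when a test table is supplied, in the test table too.  When
#' the predictor count reaches the sample count, the fit falls back to
#' seeded cross-validated ridge regression.
#'
#' @param train_table training-cohort `abundance_table`.
#' @param train_metadata training metadata with `srs2_tscore` and
#'   covariates (complete cases used).
#' @param covariates character vector of covariate columns.
#' @param min_shared_prevalence prevalence threshold (default 0.1).
#' @param test_table optional test-cohort `abundance_table` used to enforce
#'   shared prevalence.
#' @param seed seed for the ridge fold assignment.
#' @return An object of class `transfer_model`: features, coefficients,
#'   pseudocount, method (`"ols"` or `"ridge"`), covariates.
#' @export
fit_transfer_model <- function(train_table, train_metadata,
                               covariates = character(),
                               min_shared_prevalence = 0.1,
                               test_table = NULL, seed = 1) {
  m <- train_table$values[train_metadata$sample_id, , drop = FALSE]
  prev_train <- colMeans(m > 0)
  shared <- prev_train >= min_shared_prevalence
  prev_test <- NULL
  if (!is.null(test_table)) {
    prev_test <- colMeans(test_table$values > 0)
    shared <- shared & colnames(m) %in%
      names(prev_test)[prev_test >= min_shared_prevalence]
  }
  if (!any(shared)) {
    info <- data.frame(feature = colnames(m), prevalence_train = prev_train,
                       prevalence_test =
                         if (is.null(prev_test)) NA
                         else prev_test[colnames(m)])
    stop("no shared features above prevalence ", min_shared_prevalence,
         "; per-cohort prevalences:\n",
         paste(utils::capture.output(print(utils::head(info, 20))),
               collapse = "\n"))
  }
  feats <- colnames(m)[shared]
  pc <- default_pseudocount(m[, feats, drop = FALSE])
  X <- log2(m[, feats, drop = FALSE] + pc)
  cov_df <- train_metadata[, covariates, drop = FALSE]
  for (j in seq_along(cov_df))
    if (is.character(cov_df[[j]]))
      cov_df[[j]] <- as.numeric(factor(cov_df[[j]])) - 1
  Xfull <- cbind(X, as.matrix(cov_df))
  y <- train_metadata$srs2_tscore
  cc <- stats::complete.cases(Xfull) & !is.na(y)
  Xfull <- Xfull[cc, , drop = FALSE]
  y <- y[cc]
  if (ncol(Xfull) >= nrow(Xfull)) {
    message("predictors >= samples; falling back to ridge regression")
    set.seed(seed)
    cvfit <- glmnet::cv.glmnet(Xfull, y, alpha = 0, nfolds = 5)
    beta <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
    names(beta) <- c("(Intercept)", colnames(Xfull))
    method <- "ridge"
  } else {
    fit <- stats::lm(y ~ ., data = as.data.frame(Xfull))
    beta <- stats::coef(fit)
    names(beta) <- c("(Intercept)", colnames(Xfull))
    if (anyNA(beta)) {
      beta[is.na(beta)] <- 0
      warning("aliased coefficients set to zero")
    }
    method <- "ols"
  }
  structure(list(features = feats, coefficients = beta, pseudocount = pc,
                 covariates = covariates, method = method,
                 transform = "log2(abundance + pseudocount)",
                 n_train = length(y)),
            class = "transfer_model")
}

#' Predict SRS-2 scores in a new cohort
#'
#' Deterministic linear prediction on the model's transform.  Model features
#' absent from the test table are imputed as zero abundance (counted, with a
#' warning); a missing covariate is an error.
#'
#' @param model a `transfer_model`.
#' @param test_table test-cohort `abundance_table`.
#' @param test_metadata test metadata with the model's covariate columns.
#' @return Named numeric vector of predicted scores.
#' @export
predict_scores <- function(model, test_table, test_metadata) {
  m <- test_table$values[test_metadata$sample_id, , drop = FALSE]
  missing_feats <- setdiff(model$features, colnames(m))
  if (length(missing_feats)) {
    warning(length(missing_feats),
            " model feature(s) absent from test table; imputed as zero")
    zero <- matrix(0, nrow(m), length(missing_feats),
                   dimnames = list(rownames(m), missing_feats))
    m <- cbind(m, zero)
  }
  X <- log2(m[, model$features, drop = FALSE] + model$pseudocount)
  miss_cov <- setdiff(model$covariates, names(test_metadata))
  if (length(miss_cov))
    stop("covariate(s) missing in test metadata: ",
         paste(miss_cov, collapse = ", "))
  cov_df <- test_metadata[, model$covariates, drop = FALSE]
  for (j in seq_along(cov_df))
    if (is.character(cov_df[[j]]))
      cov_df[[j]] <- as.numeric(factor(cov_df[[j]])) - 1
  Xfull <- cbind(X, as.matrix(cov_df))
  beta <- model$coefficients
  pred <- beta[["(Intercept)"]] +
    as.numeric(Xfull[, names(beta)[-1], drop = FALSE] %*% beta[-1])
  stats::setNames(pred, test_metadata$sample_id)
}

#' Evaluate predictions against observed scores
#'
#' @param pred predicted scores.
#' @param observed observed scores, aligned to `pred`.
#' @return A list of class `prediction_eval`: Pearson `r` (`NA` with a
#'   warning for constant predictions), `rmse`, `mae`, `n`.
#' @export
evaluate_predictions <- function(pred, observed) {
  stopifnot(length(pred) == length(observed))
  if (length(pred) < 3) stop("need at least 3 paired observations")
  err <- pred - observed
  r <- if (stats::sd(pred) == 0) {
    warning("constant predictions: correlation undefined")
    NA_real_
  } else stats::cor(pred, observed)
  structure(list(r = r, rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
                 n = length(pred)),
            class = "prediction_eval")
}

#' @export
print.prediction_eval <- function(x, ...) {
  cat(sprintf("prediction_eval: n = %d, r = %.3f, RMSE = %.3f, MAE = %.3f\n",
              x$n, x$r, x$rmse, x$mae))
  invisible(x)
}

#' Regress SRS-2 scores on fecal metabolite concentrations
#'
#' Per metabolite: ordinary least squares of the score on the
#' log2-transformed relative concentration, unadjusted or adjusted for the
#' full covariate set.  Coefficients are score points per doubling of
#' concentration.  Concentrations must be strictly positive (NMR relative
#' concentrations are; zeros are not pseudocounted here).
#'
#' @param concentrations samples x metabolites matrix of positive relative
#'   concentrations.
#' @param metadata metadata aligned to the matrix rows (matched by
#'   `sample_id` when rownames are present).
#' @param covariates covariate columns used when `adjusted = TRUE`.
#' @param adjusted include covariates (default `FALSE`).
#' @param ci `"normal"` or `"t"` confidence bounds.
#' @return A data.frame with one row per metabolite: `metabolite`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `p`, `n`, `adjusted`.
#' @export
metabolite_regression <- function(concentrations, metadata,
                                  covariates = character(),
                                  adjusted = FALSE, ci = c("normal", "t")) {
  ci <- match.arg(ci)
  if (any(concentrations <= 0))
    stop("non-positive concentration(s); relative concentrations must be > 0")
  if (!is.null(rownames(concentrations)) && "sample_id" %in% names(metadata)) {
    common <- intersect(rownames(concentrations), metadata$sample_id)
    concentrations <- concentrations[common, , drop = FALSE]
    metadata <- metadata[match(common, metadata$sample_id), , drop = FALSE]
  }
  covs <- if (adjusted) covariates else character()
  rows <- lapply(colnames(concentrations), function(mt) {
    df <- data.frame(srs2_tscore = metadata$srs2_tscore,
                     log2_concentration = log2(concentrations[, mt]),
                     metadata[, covs, drop = FALSE])
    fit <- ols_regression(df, outcome = "srs2_tscore", ci = ci)
    cbind(metabolite = mt,
          fit[fit$term == "log2_concentration",
              c("estimate", "se", "ci_low", "ci_high", "p", "n")])
  })
  out <- do.call(rbind, rows)
  out$adjusted <- adjusted
  rownames(out) <- NULL
  out
}
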