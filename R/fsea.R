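#' Covariate-adjusted score residuals
#'
#' Residuals from the complete linear model regressing SRS-2 scores on the
#' full covariate set; by the OLS normal equations they are orthogonal to
#' every covariate column, so enrichment against them asks whether gene
#' families track the score beyond what the covariates explain.
#'
#' @param metadata data.frame with `srs2_tscore` and complete covariate
#'   columns.
#' @param covariates character vector of covariate columns.
#' @return Named numeric vector of residuals (names = `sample_id` when
#'   present, else row names).
#' @export
residualize <- function(metadata, covariates) {
  df <- data.frame(srs2_tscore = metadata$srs2_tscore,
                   metadata[, covariates, drop = FALSE])
  if (anyNA(df)) stop("incomplete covariates; impute or subset first")
  for (j in seq_along(df))
    if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  fit <- stats::lm(srs2_tscore ~ ., data = df)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient covariate design")
  stats::setNames(stats::residuals(fit),
                  metadata$sample_id %||% rownames(metadata))
}

#' Per-gene-family Pearson correlations with a measure
#'
#' Pearson correlation of every gene family's relative abundance with a
#' per-subject measure (raw SRS-2 score or covariate-adjusted residual).
#' Zero abundances count as observed zeros.  Families nonzero in fewer than
#' `min_subjects` subjects are excluded (the prevalence filter), as are
#' zero-variance families (counted, not silently lost).
#'
#' @param table an `abundance_table` of gene families.
#' @param measure named numeric vector aligned to the table's samples.
#' @param min_subjects minimum subjects with nonzero abundance (default 4).
#' @param measure_tag label (`"score"` or `"residual"`) carried in the
#'   result.
#' @return A data.frame of class `correlation_vector` with columns
#'   `feature`, `r`, `n`, `prevalence`; excluded-family counts in
#'   attributes `n_low_prevalence` and `n_zero_variance`.
#' @export
correlate_features <- function(table, measure, min_subjects = 4,
                               measure_tag = "score") {
  m <- table$values
  if (!is.null(names(measure))) {
    common <- intersect(rownames(m), names(measure))
    m <- m[common, , drop = FALSE]
    measure <- measure[common]
  }
  if (nrow(m) < 3) stop("fewer than 3 subjects")
  prev <- colSums(m > 0)
  keep <- prev >= min_subjects
  n_low <- sum(!keep)
  m <- m[, keep, drop = FALSE]
  sds <- apply(m, 2, stats::sd)
  zv <- sds == 0
  m <- m[, !zv, drop = FALSE]
  r <- as.numeric(stats::cor(m, measure))
  out <- data.frame(feature = colnames(m), r = r, n = nrow(m),
                    prevalence = prev[keep][!zv],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "measure_tag") <- measure_tag
  attr(out, "n_low_prevalence") <- n_low
  attr(out, "n_zero_variance") <- sum(zv)
  class(out) <- c("correlation_vector", "data.frame")
  out
}

#' Mann-Whitney U enrichment of a gene set
#'
#' Rank test of the correlations of gene families inside a set against the
#' correlations of all families outside it:
#' \eqn{U = \sum_{r \in in} \#\{r' \in out : r' < r\} + \tfrac12 \#ties}.
#' The two-sided p-value is exact (null Mann-Whitney distribution) when
#' `n_in * n_out <= 10000` and the correlations are tie-free, otherwise a
#' tie-corrected normal approximation without continuity correction.
#' `med` reports the median in-set correlation (or the in-minus-out median
#' difference).
#'
#' @param correlations a `correlation_vector`.
#' @param geneset character vector of UniRef90 ids defining the set.
#' @param set_name label for the output row.
#' @param med `"median"` (default) for the median in-set correlation,
#'   `"difference"` for median(in) - median(out).
#' @return One-row data.frame of class `fsea_result`: `set`, `measure`,
#'   `n_in`, `n_out`, `U`, `med`, `p`, `untestable`.
#' @export
mwu_enrichment <- function(correlations, geneset, set_name = "set",
                           med = c("median", "difference")) {
  med <- match.arg(med)
  in_set <- correlations$feature %in% geneset
  x <- correlations$r[in_set]
  y <- correlations$r[!in_set]
  tag <- attr(correlations, "measure_tag") %||% "score"
  if (length(x) == 0 || length(y) == 0) {
    return(structure(
      data.frame(set = set_name, measure = tag, n_in = length(x),
                 n_out = length(y), U = NA_real_, med = NA_real_,
                 p = NA_real_, untestable = TRUE,
                 stringsAsFactors = FALSE),
      class = c("fsea_result", "data.frame")))
  }
  stat <- mwu_test(x, y)
  medv <- if (med == "median") stats::median(x)
          else stats::median(x) - stats::median(y)
  structure(
    data.frame(set = set_name, measure = tag, n_in = length(x),
               n_out = length(y), U = stat$U, med = medv, p = stat$p,
               untestable = FALSE, stringsAsFactors = FALSE),
    class = c("fsea_result", "data.frame"))
}

# Mann-Whitney U of x vs y with exact or tie-corrected-normal two-sided p
mwu_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (!has_ties && n1 * n2 <= 10000) {
    mu <- n1 * n2 / 2
    p <- if (U > mu) 2 * (1 - stats::pwilcox(U - 1, n1, n2))
         else 2 * stats::pwilcox(U, n1, n2)
    p <- min(1, p)
  } else {
    p <- mwu_test_normal_p(x, y)
  }
  list(U = U, p = p)
}

# tie-corrected normal approximation, no continuity correction
mwu_test_normal_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Feature-set enrichment analysis against SRS-2 scores
#'
#' The full enrichment procedure: per measure (raw score and/or
#' covariate-adjusted residual), Pearson-correlate every gene family found
#' in at least `min_subjects` subjects with the measure, run the
#' Mann-Whitney U test of each catalog set's correlations against all
#' out-of-set correlations, and apply Benjamini-Hochberg FDR across sets
#' within the measure.  Call it on one (cohort x age-window) stratum at a
#' time; early and late samples are never pooled.
#'
#' @param table gene-family `abundance_table` for one stratum (one sample
#'   per subject).
#' @param metadata aligned metadata with `srs2_tscore` (and covariates when
#'   the residual measure is requested).
#' @param catalog a `geneset_catalog`.
#' @param covariates covariate columns for the residual measure.
#' @param min_subjects prevalence filter (default 4 subjects).
#' @param measures subset of `c("score", "residual")`.
#' @param fdr_threshold significance flag threshold (default q < 0.1).
#' @param med passed to [mwu_enrichment()].
#' @return A data.frame of class `fsea_result` with one row per set x
#'   measure, sorted by `q` within measure, with `significant = q < 0.1`.
#' @export
run_fsea <- function(table, metadata, catalog, covariates = character(),
                     min_subjects = 4, measures = c("score", "residual"),
                     fdr_threshold = 0.1, med = c("median", "difference")) {
  med <- match.arg(med)
  measures <- match.arg(measures, c("score", "residual"), several.ok = TRUE)
  out <- list()
  for (ms in measures) {
    if (ms == "score") {
      v <- stats::setNames(metadata$srs2_tscore, metadata$sample_id)
    } else {
      cc <- stats::complete.cases(metadata[, covariates, drop = FALSE])
      v <- residualize(metadata[cc, , drop = FALSE], covariates)
    }
    cv <- correlate_features(table, v, min_subjects = min_subjects,
                             measure_tag = ms)
    rows <- lapply(names(catalog$sets), function(s)
      mwu_enrichment(cv, catalog$sets[[s]], set_name = s, med = med))
    rows <- do.call(rbind, rows)
    testable <- !rows$untestable
    rows$q <- NA_real_
    rows$q[testable] <- bh_fdr(rows$p[testable])
    rows$significant <- !is.na(rows$q) & rows$q < fdr_threshold
    out[[ms]] <- rows[order(rows$q), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("fsea_result", "data.frame")
  res
}

#' Taxon contributions to a gene set
#'
#' Decomposes a gene set's total abundance into per-taxon shares using the
#' stratified rows: a taxon's share is its summed stratified abundance over
#' all in-set families and samples, divided by the stratified in-set total.
#' Shares sum to one (including any `unclassified` remainder) and are ranked
#' descending with lexicographic tie-breaking.
#'
#' @param table a stratified gene-family `abundance_table`.
#' @param geneset character vector of UniRef90 ids.
#' @return A data.frame `taxon`, `total`, `share`, ranked; `NULL` with a
#'   warning when the set has no stratified rows.
#' @export
taxon_contribution <- function(table, geneset) {
  st <- table$stratified
  if (is.null(st)) {
    warning("table has no stratified rows")
    return(NULL)
  }
  st <- st[st$feature_id %in% geneset, , drop = FALSE]
  if (nrow(st) == 0) {
    warning("no stratified rows for this gene set")
    return(NULL)
  }
  tot <- tapply(st$value, st$taxon, sum)
  out <- data.frame(taxon = names(tot), total = as.numeric(tot),
                    share = as.numeric(tot) / sum(tot),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$share, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}
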