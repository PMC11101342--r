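#' Construct an abundance table
#'
#' The shared container for relative-abundance profiles: a samples x features
#' numeric matrix of non-negative values, tagged with the kind of feature it
#' holds (bacterial species or UniRef90 gene families).  Gene-family tables
#' may additionally carry per-taxon stratified contributions and the
#' per-sample mass that could not be mapped to any known gene family.
#'
#' @param values numeric matrix, samples in rows, features in columns; both
#'   dimnames must be set and feature names must be unique.
#' @param feature_kind `"taxon"` or `"genefamily"`.
#' @param stratified optional data.frame with columns `feature_id`, `taxon`,
#'   `sample_id`, `value` holding per-taxon contributions to gene families.
#'   For every feature and sample the stratified values may sum to at most the
#'   unstratified value (tolerance 1e-6).
#' @param unmapped optional named numeric vector (one entry per sample) of
#'   abundance mass not assigned to any feature; kept out of the feature set
#'   but available to the normalization denominator.
#'
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values,
                            feature_kind = c("taxon", "genefamily"),
                            stratified = NULL,
                            unmapped = NULL) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x features)")
  if (is.null(dimnames(values)))
    dimnames(values) <- list(rownames(values), colnames(values))
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("`values` must have sample rownames")
  if (ncol(values) > 0 && is.null(colnames(values)))
    stop("`values` must have feature colnames")
  if (anyDuplicated(colnames(values)))
    stop("feature ids must be unique")
  if (anyDuplicated(rownames(values)))
    stop("sample ids must be unique")
  if (any(values < 0))
    stop("abundance values must be non-negative")
  if (!is.null(unmapped)) {
    unmapped <- unmapped[rownames(values)]
    if (anyNA(unmapped)) stop("`unmapped` must cover every sample")
  }
  if (!is.null(stratified)) {
    need <- c("feature_id", "taxon", "sample_id", "value")
    if (!all(need %in% names(stratified)))
      stop("`stratified` needs columns ", paste(need, collapse = ", "))
    check_stratified_sums(values, stratified)
  }
  structure(
    list(values = values, feature_kind = feature_kind,
         stratified = stratified, unmapped = unmapped),
    class = "abundance_table")
}

check_stratified_sums <- function(values, stratified, tol = 1e-6) {
  key <- paste(stratified$sample_id, stratified$feature_id, sep = "\r")
  first <- which(!duplicated(key))
  sums <- rowsum(stratified$value, factor(key, levels = key[first]))[, 1]
  parent <- values[cbind(match(stratified$sample_id[first], rownames(values)),
                         match(stratified$feature_id[first],
                               colnames(values)))]
  keep <- !is.na(parent)
  bad <- sums[keep] > parent[keep] + tol
  if (any(bad))
    stop("stratified contributions exceed the unstratified value for ",
         sum(bad), " feature/sample pairs (e.g. ",
         stratified$feature_id[first][keep][which(bad)[1]], ")")
  invisible(TRUE)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d %s features\n",
              nrow(x$values), ncol(x$values), x$feature_kind))
  if (!is.null(x$stratified))
    cat(sprintf("  stratified rows: %d (%d features)\n", nrow(x$stratified),
                length(unique(x$stratified$feature_id))))
  if (!is.null(x$unmapped))
    cat(sprintf("  UNMAPPED mass recorded (mean %.3g per sample)\n",
                mean(x$unmapped)))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Sample and feature identifiers of an abundance table
#' @param x an `abundance_table`.
#' @return character vector of identifiers.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
feature_ids <- function(x) colnames(x$values)

#' Total-sum scaling to relative abundances
#'
#' Rescales every sample so its features sum to one.  For gene-family tables
#' that recorded UNMAPPED mass, the denominator includes that mass by default,
#' so feature values are proportions of the whole community rather than of
#' the mapped fraction.  All-zero samples are left at zero and flagged in the
#' `"zero_samples"` attribute.  The operation is idempotent.
#'
#' @param x an `abundance_table`.
#' @param include_unmapped include recorded UNMAPPED mass in each sample's
#'   denominator (default `TRUE`; ignored when no UNMAPPED mass is present).
#' @return A normalized `abundance_table`; stratified values and the UNMAPPED
#'   record are rescaled by the same per-sample factor.
#' @export
tss_normalize <- function(x, include_unmapped = TRUE) {
  stopifnot(inherits(x, "abundance_table"))
  if (any(x$values < 0)) stop("negative abundance values")
  totals <- rowSums(x$values)
  if (include_unmapped && !is.null(x$unmapped))
    totals <- totals + x$unmapped
  zero <- totals <= 0
  scale <- ifelse(zero, 0, 1 / totals)
  out <- x
  out$values <- x$values * scale
  if (!is.null(x$unmapped)) out$unmapped <- x$unmapped * scale
  if (!is.null(x$stratified)) {
    s <- scale[match(x$stratified$sample_id, rownames(x$values))]
    out$stratified$value <- x$stratified$value * s
  }
  attr(out, "zero_samples") <- rownames(x$values)[zero]
  if (any(zero))
    warning(sum(zero), " all-zero sample(s) left unnormalized")
  out
}
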