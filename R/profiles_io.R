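TAX_RANKS <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
               family = "f", genus = "g", species = "s", strain = "t")

#' Read a MetaPhlAn-style taxonomic profile
#'
#' Parses the standard tab-separated layout: first column clade names with
#' `k__|p__|...|s__` lineage syntax, one column per sample.  Only rows whose
#' deepest rank matches `level` are kept, and their names are stripped to the
#' bare clade name (e.g. `Escherichia_coli`), the form used for exact
#' cross-cohort matching.  MetaPhlAn reports percentages; files whose sample
#' columns sum above 1.5 are treated as percent and rescaled to proportions,
#' so proportion-scale files pass through unchanged.
#'
#' @param path path to the TSV (comment lines starting `#` before the header
#'   are tolerated; a `#`-prefixed header is used as the header).
#' @param level taxonomic rank to extract, one of
#'   `r paste(names(TAX_RANKS), collapse = ", ")`.
#' @return An `abundance_table` with `feature_kind = "taxon"`, values on the
#'   proportion scale.
#' @export
read_taxonomic_profiles <- function(path, level = "species") {
  level <- match.arg(level, names(TAX_RANKS))
  df <- read_profile_tsv(path)
  clades <- df[[1]]
  ranks <- vapply(seq_along(clades), function(i)
    lineage_rank(clades[i], line = i), character(1))
  if (anyDuplicated(names(df)[-1]))
    stop("duplicate sample column(s): ",
         paste(unique(names(df)[-1][duplicated(names(df)[-1])]),
               collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  keep <- ranks == TAX_RANKS[[level]]
  if (!any(keep))
    warning("no rows at rank '", level, "' in ", path)
  vals <- vals[keep, , drop = FALSE]
  rownames(vals) <- sub(".*\\|?[a-z]__([^|]+)$", "\\1", clades[keep])
  # percent vs proportion auto-detection
  if (length(vals) && any(colSums(vals) > 1.5)) vals <- vals / 100
  if (length(vals) && any(colSums(vals) > 1 + 1e-6))
    stop("sample columns sum above 1 after percent rescaling")
  abundance_table(t(vals), feature_kind = "taxon")
}

lineage_rank <- function(clade, line) {
  parts <- strsplit(clade, "|", fixed = TRUE)[[1]]
  ok <- grepl("^[a-z]__.+", parts)
  if (length(parts) == 0 || !all(ok))
    stop("malformed lineage string at line ", line, ": '", clade, "'")
  prefixes <- substr(parts, 1, 1)
  if (!all(prefixes %in% TAX_RANKS))
    stop("unknown rank prefix at line ", line, ": '", clade, "'")
  prefixes[length(prefixes)]
}

read_profile_tsv <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  # MetaPhlAn/HUMAnN put the header on a '#'-prefixed line
  skip <- 0
  while (skip + 1 < length(lines) && startsWith(lines[skip + 1], "#") &&
         startsWith(lines[skip + 2], "#")) skip <- skip + 1
  lines <- lines[(skip + 1):length(lines)]
  lines[1] <- sub("^#\\s*", "", lines[1])
  utils::read.delim(text = paste(lines, collapse = "\n"),
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a taxonomic profile in MetaPhlAn-style layout
#'
#' Features are written as `s__<name>` clade rows (species level) with
#' proportion-scale values, which `read_taxonomic_profiles()` reads back
#' unchanged.
#'
#' @param x an `abundance_table` of kind `"taxon"`.
#' @param path output path.
#' @export
write_taxonomic_profiles <- function(x, path) {
  stopifnot(inherits(x, "abundance_table"), x$feature_kind == "taxon")
  df <- data.frame(clade_name = paste0("s__", colnames(x$values)),
                   t(x$values), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a HUMAnN-style gene-family profile
#'
#' Rows are `UniRef90_X` (community total) or `UniRef90_X|g__G.s__s` /
#' `UniRef90_X|unclassified` (per-taxon stratified contribution).  `UNMAPPED`
#' and `UNGROUPED` rows are excluded from the feature set but their mass is
#' recorded per sample so that normalization can use the whole-community
#' denominator.  A stratified row without a matching community-total parent
#' triggers a warning and the parent is synthesized as the sum of its strata.
#'
#' @param path path to the TSV (optionally gzipped).
#' @param keep_stratified retain stratified rows in the `stratified` slot
#'   (default `TRUE`); when `FALSE` they are dropped and only community
#'   totals are kept.
#' @return An `abundance_table` with `feature_kind = "genefamily"`, raw
#'   (unnormalized) values; apply [tss_normalize()] downstream.
#' @export
read_genefamily_profiles <- function(path, keep_stratified = TRUE) {
  df <- read_profile_tsv(path)
  ids <- df[[1]]
  if (anyDuplicated(names(df)[-1]))
    stop("duplicate sample column(s) in ", path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  samples <- colnames(vals)

  special <- ids %in% c("UNMAPPED", "UNGROUPED") |
    grepl("^(UNMAPPED|UNGROUPED)\\|", ids)
  unmapped <- if (any(special)) colSums(vals[special, , drop = FALSE]) else NULL
  ids2 <- ids[!special]
  vals <- vals[!special, , drop = FALSE]

  strat <- grepl("|", ids2, fixed = TRUE)
  parent_vals <- vals[!strat, , drop = FALSE]
  rownames(parent_vals) <- ids2[!strat]

  strat_df <- NULL
  if (any(strat)) {
    sid <- ids2[strat]
    feature <- sub("\\|.*$", "", sid)
    taxon <- strat_taxon(sub("^[^|]+\\|", "", sid))
    sv <- vals[strat, , drop = FALSE]
    orphans <- setdiff(unique(feature), rownames(parent_vals))
    if (length(orphans)) {
      warning(length(orphans), " stratified feature(s) lack a community ",
              "total row; parent synthesized as the sum of strata (e.g. ",
              orphans[1], ")")
      synth <- do.call(rbind, lapply(orphans, function(f)
        colSums(sv[feature == f, , drop = FALSE])))
      rownames(synth) <- orphans
      parent_vals <- rbind(parent_vals, synth)
    }
    if (keep_stratified)
      strat_df <- data.frame(
        feature_id = rep(feature, each = length(samples)),
        taxon = rep(taxon, each = length(samples)),
        sample_id = rep(samples, times = length(sid)),
        value = as.vector(t(sv)),
        stringsAsFactors = FALSE)
  }
  abundance_table(t(parent_vals), feature_kind = "genefamily",
                  stratified = strat_df, unmapped = unmapped)
}

strat_taxon <- function(suffix) {
  ifelse(suffix == "unclassified", "unclassified",
         sub("^.*s__", "", suffix))
}

#' Write a gene-family profile in HUMAnN-style layout
#'
#' Community totals, stratified rows and recorded UNMAPPED mass are written
#' back in the `|`-delimited layout that [read_genefamily_profiles()] parses.
#'
#' @param x an `abundance_table` of kind `"genefamily"`.
#' @param path output path.
#' @export
write_genefamily_profiles <- function(x, path) {
  stopifnot(inherits(x, "abundance_table"), x$feature_kind == "genefamily")
  samples <- rownames(x$values)
  rows <- list()
  if (!is.null(x$unmapped))
    rows[["UNMAPPED"]] <- x$unmapped
  for (f in colnames(x$values)) {
    rows[[f]] <- x$values[, f]
    if (!is.null(x$stratified)) {
      sub <- x$stratified[x$stratified$feature_id == f, , drop = FALSE]
      for (tx in unique(sub$taxon)) {
        key <- if (tx == "unclassified") paste0(f, "|unclassified")
               else paste0(f, "|g__", sub("_.*$", "", tx), ".s__", tx)
        v <- sub[sub$taxon == tx, ]
        rows[[key]] <- v$value[match(samples, v$sample_id)]
      }
    }
  }
  m <- do.call(rbind, rows)
  df <- data.frame(`# Gene Family` = names(rows), m, check.names = FALSE)
  colnames(df)[-1] <- samples
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Default covariate schema
#'
#' The covariate set used throughout the pipeline: gestational age,
#' child's sex (carried separately), peripartum antibiotic exposure, delivery
#' mode, exclusive breastfeeding at stool collection, maternal smoking during
#' pregnancy, maternal and paternal age, marital status, parity, maternal
#' education, and child's age at assessment.
#'
#' @param extra_missing_codes additional strings to treat as missing beyond
#'   `""`, `"NA"`, `"NaN"`.
#' @return A data.frame with columns `name` and `type`
#'   (`"binary"`/`"continuous"`), with the missing-value codes attached as an
#'   attribute.
#' @export
default_covariate_schema <- function(extra_missing_codes = character()) {
  sch <- data.frame(
    name = c("gestational_age", "peripartum_antibiotics", "delivery_mode",
             "breastfeeding", "maternal_smoking", "maternal_age",
             "paternal_age", "marital_status", "parity",
             "maternal_education", "age_at_srs2"),
    type = c("continuous", "binary", "binary", "binary", "binary",
             "continuous", "continuous", "binary", "binary", "binary",
             "continuous"),
    stringsAsFactors = FALSE)
  attr(sch, "missing_codes") <- c("", "NA", "NaN", extra_missing_codes)
  sch
}

#' Read a sample-metadata table
#'
#' Reads a delimited metadata table into the typed layout the analysis
#' functions expect: one row per sample, columns `subject_id`, `sample_id`,
#' `cohort`, `sex`, `srs2_tscore`, `sample_age_window`, plus the covariates
#' declared in `schema`.  Missing-value codes become `NA` (the missingness
#' mask); binary covariates must be coded 0/1.
#'
#' @param path path to a CSV or TSV file (delimiter sniffed from the header).
#' @param schema covariate schema as from [default_covariate_schema()].
#' @return A data.frame of class `sample_metadata`.
#' @export
read_metadata <- function(path, schema = default_covariate_schema()) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  codes <- attr(schema, "missing_codes")
  for (j in seq_along(df)) df[[j]][df[[j]] %in% codes] <- NA
  mandatory <- c("subject_id", "srs2_tscore")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  df$srs2_tscore <- as.numeric(df$srs2_tscore)
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (!nm %in% names(df)) next
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (any(!is.na(df[[nm]]) & is.na(v)))
      stop("non-numeric values in covariate '", nm, "'")
    if (schema$type[i] == "binary") {
      bad <- which(!is.na(v) & !v %in% c(0, 1))
      if (length(bad))
        stop("unknown level in binary covariate '", nm, "' at row(s) ",
             paste(utils::head(bad, 5), collapse = ", "))
    }
    df[[nm]] <- v
  }
  if (!"cohort" %in% names(df)) df$cohort <- "A"
  if (!"sample_age_window" %in% names(df)) df$sample_age_window <- "early"
  key <- interaction(df$cohort, df$sample_age_window, df$subject_id,
                     drop = TRUE)
  if (anyDuplicated(key)) {
    d <- df$subject_id[duplicated(key)]
    stop("duplicate subject_id within cohort/window: ",
         paste(unique(d), collapse = ", "))
  }
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Summarize covariate missingness
#' @param metadata a `sample_metadata` data.frame.
#' @param schema covariate schema.
#' @return Named integer vector of missing counts per covariate.
#' @export
missingness_summary <- function(metadata, schema = default_covariate_schema()) {
  covs <- intersect(schema$name, names(metadata))
  vapply(covs, function(nm) sum(is.na(metadata[[nm]])), integer(1))
}

#' Write a sample-metadata table
#' @param metadata a `sample_metadata` data.frame.
#' @param path output CSV path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE, na = "NA")
}

#' Load a neuroactive gene-set catalog
#'
#' Reads a catalog of named KEGG-Ortholog sets and a KO-to-UniRef90 mapping
#' table and resolves every set to UniRef90 membership (the union over its
#' KOs).  KOs absent from the mapping are counted per set, not fatal; a set
#' whose every KO is unmapped is flagged empty but never silently dropped.
#'
#' @param sets_path TSV with columns `set_name`, `ko` (one pair per line).
#' @param mapping_path TSV with columns `ko`, `uniref90` (one pair per line;
#'   gzip allowed).
#' @return An object of class `geneset_catalog`: list with `sets` (named list
#'   of UniRef90 character vectors), `ko_members`, `mapping`, `unmapped_kos`
#'   (per-set count), `empty_sets`.
#' @export
load_geneset_catalog <- function(sets_path, mapping_path) {
  sets_df <- utils::read.delim(sets_path, stringsAsFactors = FALSE)
  names(sets_df) <- tolower(names(sets_df))
  stopifnot(all(c("set_name", "ko") %in% names(sets_df)))
  con <- if (grepl("\\.gz$", mapping_path)) gzfile(mapping_path)
         else file(mapping_path)
  map_df <- utils::read.delim(con, stringsAsFactors = FALSE)
  names(map_df) <- tolower(names(map_df))
  stopifnot(all(c("ko", "uniref90") %in% names(map_df)))
  mapping <- split(map_df$uniref90, map_df$ko)
  ko_members <- lapply(split(sets_df$ko, sets_df$set_name), unique)
  sets <- lapply(ko_members, function(kos)
    unique(unlist(mapping[intersect(kos, names(mapping))], use.names = FALSE)))
  unmapped <- vapply(ko_members, function(kos)
    sum(!kos %in% names(mapping)), integer(1))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty))
    warning("gene set(s) with no mapped UniRef90 members: ",
            paste(empty, collapse = ", "))
  structure(list(sets = sets, ko_members = ko_members, mapping = mapping,
                 unmapped_kos = unmapped, empty_sets = empty),
            class = "geneset_catalog")
}

#' @export
print.geneset_catalog <- function(x, ...) {
  cat(sprintf("geneset_catalog: %d sets, %d mapped KOs\n",
              length(x$sets), length(x$mapping)))
  invisible(x)
}
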