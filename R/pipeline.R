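#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: either a synthetic-cohort
#' simulation config or paths to profile/metadata files, the covariate list,
#' the analysis thresholds, permutation count and output directory.
#' Age-window assignment uses half-open intervals on sample age:
#' early = \[0, 6) months, late = \[6, 24\] months.
#'
#' @param out_dir output directory for the result bundle.
#' @param seed integer seed; mandatory, drives every stochastic stage.
#' @param synthetic optional [simulation_config()]; when supplied the
#'   cohort is generated rather than read.
#' @param taxonomic_path,genefamily_path,metadata_path,metabolite_path input
#'   files (used when `synthetic` is `NULL`).
#' @param sets_path,mapping_path gene-set catalog files (when not
#'   synthetic).
#' @param covariates adjustment covariate columns used by every model.
#' @param permanova_terms design terms for the PERMANOVA stage.
#' @param min_subjects FSEA prevalence filter (default 4 subjects).
#' @param fdr_threshold FDR significance threshold (default 0.1).
#' @param min_prevalence screen prevalence filter (default 0.1).
#' @param n_permutations PERMANOVA permutations (default 9999).
#' @param impute_m multiple-imputation copies for pooled hit regressions
#'   (default 20; 0 disables the imputation pass).
#' @param early_max_months,late_max_months window bounds.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed, synthetic = NULL,
                            taxonomic_path = NULL, genefamily_path = NULL,
                            metadata_path = NULL, metabolite_path = NULL,
                            sets_path = NULL, mapping_path = NULL,
                            covariates = c("gestational_age", "sex",
                                           "peripartum_antibiotics",
                                           "delivery_mode", "breastfeeding",
                                           "maternal_smoking",
                                           "maternal_age", "paternal_age",
                                           "marital_status", "parity",
                                           "maternal_education",
                                           "age_at_srs2"),
                            permanova_terms = c("srs2_tscore", "sex"),
                            min_subjects = 4, fdr_threshold = 0.1,
                            min_prevalence = 0.1, n_permutations = 9999,
                            impute_m = 20,
                            early_max_months = 6, late_max_months = 24) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  stopifnot(min_subjects >= 1, fdr_threshold > 0, fdr_threshold <= 1,
            min_prevalence >= 0, min_prevalence < 1, n_permutations >= 99)
  if (is.null(synthetic) &&
      (is.null(taxonomic_path) || is.null(metadata_path)))
    stop("either `synthetic` or input paths must be given")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, for every cohort x age-window stratum: Bray-Curtis PERMANOVA,
#' Shannon and inverse-Simpson diversity regressions, the per-species
#' association screen with reverse per-doubling regressions (complete-case
#' and Rubin-pooled multiple imputation) and sex-interaction models for FDR
#' hits, and gene-set enrichment (FSEA) on raw scores and residuals.  Then
#' cross-cohort transfer prediction (first cohort trains, others test) and
#' metabolite regressions.  Writes TSV outputs plus a `manifest.json` with
#' seeds, thresholds, row counts and content hashes; a stage failure halts
#' the run, naming the stage in the error and leaving a partial manifest.
#'
#' @param config a `pipeline_config`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("gutsea")),
                   seed = config$seed,
                   thresholds = list(min_subjects = config$min_subjects,
                                     fdr = config$fdr_threshold,
                                     min_prevalence = config$min_prevalence,
                                     n_permutations = config$n_permutations),
                   stages = list(), outputs = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- "failed"
      write_manifest(manifest, config$out_dir)
      stop("pipeline halted at stage '", name, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }

  dat <- stage("load", load_pipeline_inputs(config))
  md <- dat$metadata
  manifest$stages$load <- list(
    n_samples = nrow(md), n_subjects = length(unique(md$subject_id)),
    n_species = ncol(dat$taxonomic$values),
    n_genefamilies = ncol(dat$genefamilies$values))

  strata <- unique(md[, c("cohort", "sample_age_window")])
  perm_rows <- list(); div_rows <- list(); screen_rows <- list()
  hit_rows <- list(); fsea_rows <- list()
  for (i in seq_len(nrow(strata))) {
    co <- strata$cohort[i]; w <- strata$sample_age_window[i]
    tag <- paste(co, w, sep = "_")
    sel <- md$cohort == co & md$sample_age_window == w
    smd <- md[sel, , drop = FALSE]
    tax <- subset_samples(dat$taxonomic, smd$sample_id)
    gf <- subset_samples(dat$genefamilies, smd$sample_id)
    message(sprintf("[%s] %d samples", tag, nrow(smd)))

    perm_rows[[tag]] <- stage(paste0("permanova_", tag), {
      res <- permanova_marginal(bray_curtis(tax), smd,
                                config$permanova_terms,
                                config$n_permutations,
                                seed = config$seed + 100L + i)
      cbind(cohort = co, window = w, res)
    })
    div_rows[[tag]] <- stage(paste0("diversity_", tag), {
      rows <- lapply(c("shannon", "inverse_simpson"), function(idx) {
        dv <- alpha_diversity_table(tax, idx)
        cc <- stats::complete.cases(smd[, config$covariates, drop = FALSE])
        fit <- diversity_regression(dv[cc], smd[cc, , drop = FALSE],
                                    config$covariates)
        cbind(cohort = co, window = w, index = idx,
              fit[fit$term == "diversity_sd", ])
      })
      do.call(rbind, rows)
    })
    scr_out <- stage(paste0("screen_", tag), {
      cc <- stats::complete.cases(smd[, config$covariates, drop = FALSE])
      scr <- feature_screen(tax, smd[cc, , drop = FALSE],
                            config$covariates,
                            min_prevalence = config$min_prevalence)
      hits <- scr$feature[scr$q < config$fdr_threshold]
      list(screen = cbind(cohort = co, window = w, scr),
           hits = lapply(hits, function(f)
             stratum_hit_models(f, tax, smd, config, co, w)))
    })
    screen_rows[[tag]] <- scr_out$screen
    hit_rows[[tag]] <- scr_out$hits
    fsea_rows[[tag]] <- stage(paste0("fsea_", tag), {
      cc <- stats::complete.cases(smd[, config$covariates, drop = FALSE])
      measures <- if (sum(cc) >= length(config$covariates) + 3)
        c("score", "residual") else "score"
      res <- run_fsea(gf, smd[cc, , drop = FALSE], dat$catalog,
                      config$covariates, config$min_subjects,
                      measures = measures,
                      fdr_threshold = config$fdr_threshold)
      cbind(cohort = co, window = w, res)
    })
  }

  transfer_rows <- stage("transfer", {
    cohorts <- unique(md$cohort)
    rows <- list()
    if (length(cohorts) >= 2) {
      for (w in unique(md$sample_age_window)) {
        tr <- md$cohort == cohorts[1] & md$sample_age_window == w
        te <- md$cohort == cohorts[2] & md$sample_age_window == w
        if (sum(tr) < 10 || sum(te) < 10) next
        tmd <- md[tr, , drop = FALSE]
        emd <- md[te, , drop = FALSE]
        tcc <- stats::complete.cases(tmd[, config$covariates, drop = FALSE])
        ecc <- stats::complete.cases(emd[, config$covariates, drop = FALSE])
        model <- fit_transfer_model(
          subset_samples(dat$taxonomic, tmd$sample_id[tcc]),
          tmd[tcc, , drop = FALSE], config$covariates,
          min_shared_prevalence = config$min_prevalence,
          test_table = subset_samples(dat$taxonomic, emd$sample_id[ecc]),
          seed = config$seed + 200L)
        pred <- predict_scores(model,
                               subset_samples(dat$taxonomic,
                                              emd$sample_id[ecc]),
                               emd[ecc, , drop = FALSE])
        ev <- evaluate_predictions(pred, emd$srs2_tscore[ecc])
        rows[[w]] <- data.frame(
          train = cohorts[1], test = cohorts[2], window = w,
          method = model$method, n_features = length(model$features),
          r = ev$r, rmse = ev$rmse, mae = ev$mae, n = ev$n,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(train = character(), test = character(),
                 window = character(), method = character(),
                 n_features = integer(), r = numeric(), rmse = numeric(),
                 mae = numeric(), n = integer())
  })

  metab_rows <- stage("metabolites", {
    if (is.null(dat$metabolites)) NULL else {
      mmd <- md[match(rownames(dat$metabolites), md$sample_id), ,
                drop = FALSE]
      cc <- stats::complete.cases(mmd[, config$covariates, drop = FALSE])
      un <- metabolite_regression(dat$metabolites, mmd)
      ad <- metabolite_regression(dat$metabolites[cc, , drop = FALSE],
                                  mmd[cc, , drop = FALSE],
                                  config$covariates, adjusted = TRUE)
      rbind(un, ad)
    }
  })

  outputs <- list(
    permanova.tsv = do.call(rbind, perm_rows),
    diversity.tsv = do.call(rbind, div_rows),
    screen.tsv = do.call(rbind, screen_rows),
    screen_hits.tsv = {
      h <- unlist(hit_rows, recursive = FALSE)
      if (length(h)) do.call(rbind, h) else
        data.frame(cohort = character(), window = character(),
                   feature = character(), model = character(),
                   estimate = numeric(), se = numeric(),
                   ci_low = numeric(), ci_high = numeric(), p = numeric(),
                   p_interaction = numeric())
    },
    fsea.tsv = do.call(rbind, fsea_rows),
    transfer_eval.tsv = transfer_rows)
  if (!is.null(metab_rows)) outputs$metab.tsv <- metab_rows
  for (nm in names(outputs)) {
    path <- file.path(config$out_dir, nm)
    utils::write.table(outputs[[nm]], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$outputs[[nm]] <- list(
      rows = nrow(outputs[[nm]]),
      md5 = unname(tools::md5sum(path)))
    manifest$stages[[sub("\\.tsv$", "", nm)]] <- "ok"
  }
  write_manifest(manifest, config$out_dir)
  invisible(manifest)
}

# reverse regressions (complete-case + Rubin-pooled imputation) and the
# sex-interaction model for one screen hit
stratum_hit_models <- function(f, tax, smd, config, co, w) {
  pc <- default_pseudocount(tax)
  fv <- tax$values[smd$sample_id, f]
  cc <- stats::complete.cases(smd[, config$covariates, drop = FALSE])
  rev_cc <- reverse_regression(fv[cc], smd[cc, , drop = FALSE],
                               config$covariates, pseudocount = pc)
  rev_cc <- rev_cc[rev_cc$term == "log2_abundance", ]
  p_int <- tryCatch(
    interaction_model(fv[cc], smd[cc, , drop = FALSE],
                      config$covariates, pseudocount = pc)$p_interaction,
    error = function(e) NA_real_)
  rows <- data.frame(cohort = co, window = w, feature = f,
                     model = "complete_case",
                     rev_cc[, c("estimate", "se", "ci_low", "ci_high", "p")],
                     p_interaction = p_int, stringsAsFactors = FALSE)
  if (config$impute_m > 0 &&
      anyNA(smd[, intersect(config$covariates, names(smd))])) {
    covs_imp <- intersect(default_covariate_schema()$name, config$covariates)
    imp <- impute_covariates(smd, covariates = covs_imp, m = config$impute_m,
                             seed = config$seed + 300L)
    fits <- lapply(imp$copies, function(cp) {
      r <- reverse_regression(fv, cp, config$covariates, pseudocount = pc)
      r[r$term == "log2_abundance", ]
    })
    pooled <- pool_rubin(lapply(fits, function(x) c(log2_abundance =
                                                      x$estimate)),
                         lapply(fits, function(x) c(log2_abundance =
                                                      x$se^2)))
    rows <- rbind(rows, data.frame(
      cohort = co, window = w, feature = f, model = "imputed",
      pooled[, c("estimate", "se", "ci_low", "ci_high", "p")],
      p_interaction = NA_real_, stringsAsFactors = FALSE))
  }
  rows
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    ch <- generate_cohort(config$synthetic)
    return(list(metadata = ch$metadata, taxonomic = ch$taxonomic,
                genefamilies = ch$genefamilies,
                metabolites = ch$metabolites, catalog = ch$catalog))
  }
  md <- read_metadata(config$metadata_path)
  if (!"sample_age_window" %in% names(md) &&
      "sample_age_months" %in% names(md))
    md$sample_age_window <- assign_age_window(md$sample_age_months,
                                              config$early_max_months,
                                              config$late_max_months)
  tax <- read_taxonomic_profiles(config$taxonomic_path)
  gf <- if (!is.null(config$genefamily_path))
    tss_normalize(read_genefamily_profiles(config$genefamily_path))
  else NULL
  catalog <- if (!is.null(config$sets_path))
    load_geneset_catalog(config$sets_path, config$mapping_path)
  else NULL
  mtb <- if (!is.null(config$metabolite_path)) {
    m <- utils::read.delim(config$metabolite_path, check.names = FALSE)
    mm <- as.matrix(m[, -1, drop = FALSE])
    rownames(mm) <- m[[1]]
    mm
  } else NULL
  list(metadata = md, taxonomic = tax, genefamilies = gf,
       metabolites = mtb, catalog = catalog)
}

#' Assign early/late age windows
#'
#' Half-open early window \[0, `early_max`) months, late window
#' \[`early_max`, `late_max`\] months; ages beyond `late_max` get `NA`.
#'
#' @param age_months sample age in months.
#' @param early_max,late_max window bounds (defaults 6 and 24 months).
#' @return Character vector `"early"`/`"late"`/`NA`.
#' @export
assign_age_window <- function(age_months, early_max = 6, late_max = 24) {
  ifelse(age_months < early_max, "early",
         ifelse(age_months <= late_max, "late", NA_character_))
}

#' Subset an abundance table to a set of samples
#' @param table an `abundance_table`.
#' @param ids sample ids to keep (order preserved).
#' @return An `abundance_table` restricted to those samples.
#' @export
subset_samples <- function(table, ids) {
  stopifnot(all(ids %in% rownames(table$values)))
  out <- table
  out$values <- table$values[ids, , drop = FALSE]
  if (!is.null(table$unmapped)) out$unmapped <- table$unmapped[ids]
  if (!is.null(table$stratified))
    out$stratified <- table$stratified[
      table$stratified$sample_id %in% ids, , drop = FALSE]
  out
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
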