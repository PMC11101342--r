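#' Simulation configuration for a synthetic two-cohort study
#'
#' Defines the statistical structure of a synthetic birth-cohort study:
#' two cohorts (defaults 200 and 90 subjects), early (< 6 months) and late
#' (6 months - 2 years) stool samples per subject, a Table-1-style covariate
#' set with missing-completely-at-random masks, SRS-2 T-scores built from a
#' per-cohort intercept, covariate effects, planted microbiome/metabolite
#' effects and Gaussian noise, sparse compositional species and gene-family
#' tables, and planted in-set correlations for gene-set enrichment.
#'
#' Planted effects use the scales the analyses report: `planted_species` and
#' `planted_metabolites` are T-score points per doubling of relative
#' abundance/concentration (applied to log2-transformed values);
#' `planted_sets` are target Pearson correlations (on the log scale, before
#' sparsification) between each in-set gene family and the score.
#'
#' @param seed integer seed; mandatory, drives every random draw.
#' @param n_subjects named integer vector of subjects per cohort.
#' @param windows sample age windows to generate per subject.
#' @param n_species,n_genefamilies,n_metabolites table dimensions.
#' @param n_sets,set_size gene-set catalog shape (count, size range).
#' @param score_intercept,score_noise_sd per-cohort SRS-2 intercept and
#'   residual SD (T-score units).
#' @param covariate_effects named numeric vector of score effects per
#'   covariate (continuous covariates are centered at their marginal mean
#'   before the effect is applied); may include `"sex"` (male = 1).
#' @param planted_species named numeric vector, T-score points per doubling
#'   of the named species' relative abundance.
#' @param planted_sets named numeric vector of in-set correlation targets,
#'   names matching catalog set names.
#' @param planted_metabolites named numeric vector, T-score points per
#'   doubling of the named metabolite's relative concentration.
#' @param confound_breastfeeding_metabolite effect of formula feeding
#'   (breastfeeding = 0) on the first planted metabolite's log2
#'   concentration; together with a breastfeeding term in
#'   `covariate_effects` this creates the attenuation-on-adjustment pattern.
#' @param sparsity named expected zero fraction for `taxon` and `genefamily`
#'   tables.
#' @param dispersion named SD of log-scale abundances.
#' @param stratify_genefamilies generate per-taxon stratified rows for
#'   in-catalog gene families (default `TRUE`; disable for large
#'   calibration sweeps that never touch taxon contributions).
#' @param missingness named per-covariate MCAR missingness rates.
#' @return A `simulation_config` list, validated.
#' @export
simulation_config <- function(
    seed,
    n_subjects = c(A = 200, B = 90),
    windows = c("early", "late"),
    n_species = 100,
    n_genefamilies = 2000,
    n_metabolites = 10,
    n_sets = 30,
    set_size = c(20, 60),
    score_intercept = c(A = 43.6, B = 49.9),
    score_noise_sd = c(A = 4.8, B = 8.5),
    covariate_effects = c(breastfeeding = -2),
    planted_species = c(species_001 = 0.41),
    planted_sets = c(synthetic_set_01 = 0.15),
    planted_metabolites = c(butyrate = 0.86),
    confound_breastfeeding_metabolite = 1.5,
    sparsity = c(taxon = 0.6, genefamily = 0.3),
    dispersion = c(taxon = 2, genefamily = 1.5),
    stratify_genefamilies = TRUE,
    missingness = c(paternal_age = 0.024, maternal_smoking = 0.014,
                    maternal_education = 0.028, marital_status = 0.028,
                    parity = 0.014, delivery_mode = 0.024,
                    breastfeeding = 0.104, peripartum_antibiotics = 0.024)) {
  if (missing(seed) || is.null(seed))
    stop("`seed` is mandatory")
  stopifnot(all(n_subjects >= 1), n_species >= 1, n_genefamilies >= 1,
            n_sets >= 1, length(set_size) == 2,
            all(sparsity >= 0 & sparsity < 1),
            all(abs(planted_sets) < 1),
            all(missingness >= 0 & missingness < 1))
  if (max(set_size) > n_genefamilies)
    stop("set size exceeds n_genefamilies")
  cfg <- list(seed = as.integer(seed), n_subjects = n_subjects,
              windows = windows, n_species = n_species,
              n_genefamilies = n_genefamilies, n_metabolites = n_metabolites,
              n_sets = n_sets, set_size = set_size,
              score_intercept = score_intercept,
              score_noise_sd = score_noise_sd,
              covariate_effects = covariate_effects,
              planted_species = planted_species,
              planted_sets = planted_sets,
              planted_metabolites = planted_metabolites,
              confound_breastfeeding_metabolite =
                confound_breastfeeding_metabolite,
              sparsity = sparsity, dispersion = dispersion,
              stratify_genefamilies = stratify_genefamilies,
              missingness = missingness)
  class(cfg) <- "simulation_config"
  cfg
}

# Table-1-style covariate marginals (NHBCS-like): mean/sd for continuous,
# success probability for binary.
covariate_marginals <- function() {
  list(
    gestational_age = list(type = "continuous", mean = 39.2, sd = 1.7),
    peripartum_antibiotics = list(type = "binary", p = 0.54),
    delivery_mode = list(type = "binary", p = 0.27),
    breastfeeding = list(type = "binary", p = 0.59),
    maternal_smoking = list(type = "binary", p = 0.045),
    maternal_age = list(type = "continuous", mean = 32.4, sd = 4.2),
    paternal_age = list(type = "continuous", mean = 33.9, sd = 5.8),
    marital_status = list(type = "binary", p = 0.89),
    parity = list(type = "binary", p = 0.50),
    maternal_education = list(type = "binary", p = 0.44),
    age_at_srs2 = list(type = "continuous", mean = 3.2, sd = 0.4))
}

#' Generate a synthetic gene-set catalog
#'
#' Builds a catalog of named sets over synthetic UniRef90 identifiers, with
#' a 1:1 KO-to-UniRef90 mapping, shaped like a resolved neuroactive-module
#' catalog.  Sets are sampled independently, so overlap is possible.
#'
#' @param config a `simulation_config`.
#' @return A `geneset_catalog`.
#' @export
make_synthetic_catalog <- function(config) {
  set.seed(config$seed + 5L)
  fams <- sprintf("UniRef90_SYN%05d", seq_len(config$n_genefamilies))
  kos <- sprintf("K%05d", seq_len(config$n_genefamilies))
  mapping <- as.list(fams)
  names(mapping) <- kos
  sizes <- sample(config$set_size[1]:config$set_size[2], config$n_sets,
                  replace = TRUE)
  sets <- lapply(sizes, function(sz) sample(fams, sz))
  names(sets) <- sprintf("synthetic_set_%02d", seq_len(config$n_sets))
  ko_members <- lapply(sets, function(s) kos[match(s, fams)])
  structure(list(sets = sets, ko_members = ko_members, mapping = mapping,
                 unmapped_kos = stats::setNames(integer(config$n_sets),
                                                names(sets)),
                 empty_sets = character()),
            class = "geneset_catalog")
}

#' Generate synthetic sample metadata
#'
#' Draws per-subject covariates from Table-1-style marginals, builds the
#' base SRS-2 T-score (intercept + covariate effects + Gaussian noise;
#' planted microbiome and metabolite contributions are added later by the
#' profile generators through the truth record), emits one row per subject
#' and age window, and applies MCAR missingness masks at the configured
#' rates.  Missingness is applied after the score is formed, so masked
#' covariates still acted on the score.
#'
#' @param config a `simulation_config`.
#' @return A `sample_metadata` data.frame; true (pre-mask) covariates and the
#'   base score are stored in the `"truth"` attribute.
#' @export
generate_metadata <- function(config) {
  set.seed(config$seed + 1L)
  marg <- covariate_marginals()
  rows <- list()
  truth_rows <- list()
  for (co in names(config$n_subjects)) {
    n <- config$n_subjects[[co]]
    subj <- sprintf("%s_%03d", co, seq_len(n))
    sex <- ifelse(stats::rbinom(n, 1, 0.56) == 1, "male", "female")
    covs <- lapply(marg, function(m)
      if (m$type == "binary") stats::rbinom(n, 1, m$p)
      else stats::rnorm(n, m$mean, m$sd))
    covs <- as.data.frame(covs)
    eff <- rep(0, n)
    for (nm in names(config$covariate_effects)) {
      b <- config$covariate_effects[[nm]]
      x <- if (nm == "sex") as.numeric(sex == "male")
           else if (nm %in% names(covs)) {
             m <- marg[[nm]]
             if (m$type == "continuous") covs[[nm]] - m$mean else covs[[nm]]
           } else stop("covariate effect on unknown covariate: ", nm)
      eff <- eff + b * x
    }
    base <- config$score_intercept[[co]] + eff +
      stats::rnorm(n, 0, config$score_noise_sd[[co]])
    age_by_window <- list(early = stats::runif(n, 1, 5.9),
                          late = stats::runif(n, 6.5, 23))
    masked <- covs
    for (nm in names(config$missingness)) {
      if (!nm %in% names(masked)) next
      hit <- stats::runif(n) < config$missingness[[nm]]
      masked[[nm]][hit] <- NA
    }
    for (w in config$windows) {
      rows[[paste(co, w)]] <- data.frame(
        subject_id = subj,
        sample_id = paste0(subj, "_", w),
        cohort = co, sex = sex,
        srs2_tscore = base,
        sample_age_window = w,
        sample_age_months = age_by_window[[w]],
        masked, stringsAsFactors = FALSE)
    }
    truth_rows[[co]] <- data.frame(subject_id = subj, base_score = base,
                                   covs, stringsAsFactors = FALSE)
  }
  md <- do.call(rbind, rows)
  rownames(md) <- md$sample_id
  class(md) <- c("sample_metadata", "data.frame")
  attr(md, "truth") <- do.call(rbind, truth_rows)
  md
}

# shared log-normal + sparsify machinery; returns normalized abundance_table
# plus the realized pseudocount
lognormal_table <- function(n_features, feature_names, log_matrix, sparsity) {
  vals <- exp(log_matrix)
  zero <- matrix(stats::runif(length(vals)) < sparsity, nrow(vals))
  vals[zero] <- 0
  dead <- rowSums(vals) == 0
  if (any(dead)) {
    # one resampling pass of the zero mask for all-zero samples
    for (i in which(dead)) {
      zmask <- stats::runif(n_features) < sparsity
      vals[i, ] <- exp(log_matrix[i, ]) * !zmask
    }
    still <- rowSums(vals) == 0
    if (any(still)) warning(sum(still), " all-zero sample(s) after resampling")
  }
  vals
}

#' Generate a synthetic species abundance table
#'
#' Per-sample log-normal intensities with configured dispersion, Bernoulli
#' zeroing at the sparsity rate, then total-sum scaling.  For each planted
#' species the per-subject score contribution
#' `beta * log2(relative abundance + pseudocount)` (averaged over the
#' subject's sample windows) is returned in the truth attribute; the cohort
#' assembler adds it to the score before gene families are generated.
#'
#' @param config a `simulation_config`.
#' @param metadata output of [generate_metadata()].
#' @return An `abundance_table` (kind `"taxon"`, TSS-normalized) with a
#'   `"truth"` attribute holding per-subject score increments and the
#'   pseudocount used.
#' @export
generate_taxonomic <- function(config, metadata) {
  set.seed(config$seed + 2L)
  n <- nrow(metadata)
  sp <- sprintf("species_%03d", seq_len(config$n_species))
  mu <- stats::rnorm(config$n_species, 0, 1.5)
  L <- matrix(mu, n, config$n_species, byrow = TRUE) +
    config$dispersion[["taxon"]] *
      matrix(stats::rnorm(n * config$n_species), n)
  vals <- lognormal_table(config$n_species, sp, L,
                          config$sparsity[["taxon"]])
  dimnames(vals) <- list(metadata$sample_id, sp)
  tab <- tss_normalize(abundance_table(vals, "taxon"))
  pc <- half_min_nonzero(tab$values)
  incr_sample <- rep(0, n)
  for (nm in names(config$planted_species)) {
    if (!nm %in% sp) stop("planted species not in table: ", nm)
    la <- log2(tab$values[, nm] + pc)
    # centered so planting shifts slopes, not the marginal score mean
    incr_sample <- incr_sample + config$planted_species[[nm]] * (la - mean(la))
  }
  incr <- tapply(incr_sample, metadata$subject_id, mean)
  attr(tab, "truth") <- list(pseudocount = pc,
                             score_increment = incr[
                               unique(metadata$subject_id)])
  tab
}

half_min_nonzero <- function(m) {
  nz <- m[m > 0]
  if (!length(nz)) return(.Machine$double.eps)
  min(nz) / 2
}

#' Generate a synthetic gene-family table with planted set enrichment
#'
#' Out-of-set families are null log-normals.  For a set with planted
#' correlation target delta, each in-set family's log abundance is built as
#' `delta * z(score) + sqrt(1 - delta^2) * noise`, so its expected Pearson
#' correlation with the score on the log scale, before sparsification, is
#' delta.  Families belonging to any catalog set receive stratified
#' contributions split across 1-3 species by Dirichlet weights (weights
#' fixed per family, so strata sum exactly to the community total).
#'
#' @param config a `simulation_config`.
#' @param metadata metadata with final scores (see [generate_cohort()]).
#' @param catalog a `geneset_catalog`, e.g. [make_synthetic_catalog()].
#' @return An `abundance_table` (kind `"genefamily"`, TSS-normalized, with
#'   stratified rows for in-catalog families).
#' @export
generate_genefamilies <- function(config, metadata, catalog) {
  set.seed(config$seed + 3L)
  n <- nrow(metadata)
  fams <- sprintf("UniRef90_SYN%05d", seq_len(config$n_genefamilies))
  z <- as.numeric(scale(metadata$srs2_tscore))
  delta <- rep(0, config$n_genefamilies)
  names(delta) <- fams
  for (s in names(config$planted_sets)) {
    if (!s %in% names(catalog$sets)) stop("planted set not in catalog: ", s)
    memb <- intersect(catalog$sets[[s]], fams)
    delta[memb] <- config$planted_sets[[s]]
  }
  mu <- stats::rnorm(config$n_genefamilies, 0, 1)
  eps <- matrix(stats::rnorm(n * config$n_genefamilies), n)
  disp <- config$dispersion[["genefamily"]]
  L <- matrix(mu, n, config$n_genefamilies, byrow = TRUE) +
    disp * (outer(z, delta) +
              sweep(eps, 2, sqrt(1 - delta^2), `*`))
  vals <- lognormal_table(config$n_genefamilies, fams, L,
                          config$sparsity[["genefamily"]])
  dimnames(vals) <- list(metadata$sample_id, fams)

  in_catalog <- if (isFALSE(config$stratify_genefamilies)) character()
                else intersect(unique(unlist(catalog$sets,
                                             use.names = FALSE)), fams)
  strat <- NULL
  if (length(in_catalog)) {
    sp <- sprintf("species_%03d", seq_len(config$n_species))
    pieces <- lapply(in_catalog, function(f) {
      k <- sample(1:3, 1)
      taxa <- sample(sp, k)
      w <- stats::rgamma(k, 2)
      w <- w / sum(w)
      data.frame(feature_id = f,
                 taxon = rep(taxa, each = n),
                 sample_id = rep(rownames(vals), times = k),
                 value = as.vector(outer(vals[, f], w)),
                 stringsAsFactors = FALSE)
    })
    strat <- do.call(rbind, pieces)
  }
  tab <- abundance_table(vals, "genefamily", stratified = strat)
  tss_normalize(tab)
}

#' Generate synthetic fecal metabolite concentrations
#'
#' Log-normal relative concentrations for early-window samples of the first
#' cohort (emulating an NMR subset).  Each planted metabolite contributes
#' `beta * log2(concentration)` to its subject's score (via the truth
#' record).  When `confound_breastfeeding_metabolite` is nonzero, formula
#' feeding (breastfeeding = 0) raises the first planted metabolite's log2
#' concentration by that amount, creating a confounding path whenever
#' breastfeeding also carries a direct score effect.
#'
#' @param config a `simulation_config`.
#' @param metadata output of [generate_metadata()].
#' @return A samples x metabolites matrix of strictly positive relative
#'   concentrations with a `"truth"` attribute of per-subject score
#'   increments.
#' @export
generate_metabolites <- function(config, metadata) {
  set.seed(config$seed + 4L)
  co <- names(config$n_subjects)[1]
  w <- config$windows[1]
  sel <- metadata$cohort == co & metadata$sample_age_window == w
  md <- metadata[sel, , drop = FALSE]
  n <- nrow(md)
  nm_planted <- names(config$planted_metabolites)
  base_names <- unique(c(nm_planted, "acetate", "propionate"))
  extra <- max(0, config$n_metabolites - length(base_names))
  mets <- c(base_names, sprintf("metabolite_%02d", seq_len(extra)))
  mets <- mets[seq_len(config$n_metabolites)]
  log2c <- matrix(stats::rnorm(n * length(mets), mean = 4, sd = 1.5), n,
                  dimnames = list(md$sample_id, mets))
  bf <- attr(metadata, "truth")
  cf <- config$confound_breastfeeding_metabolite
  if (length(nm_planted) && cf != 0 && !is.null(bf)) {
    bfv <- bf$breastfeeding[match(md$subject_id, bf$subject_id)]
    log2c[, nm_planted[1]] <- log2c[, nm_planted[1]] + cf * (1 - bfv)
  }
  incr_sample <- rep(0, n)
  for (nm in nm_planted)
    incr_sample <- incr_sample +
      config$planted_metabolites[[nm]] * (log2c[, nm] - mean(log2c[, nm]))
  conc <- 2^log2c
  incr <- stats::setNames(incr_sample, md$subject_id)
  attr(conc, "truth") <- list(score_increment = incr)
  conc
}

#' Generate a complete synthetic cohort
#'
#' Orchestrates the four generators and the score assembly: base score from
#' covariates and noise, plus planted species and metabolite contributions,
#' then gene families planted against the final score.  Identical
#' config + seed reproduces the cohort exactly.
#'
#' @param config a `simulation_config`.
#' @param catalog optional `geneset_catalog`; defaults to
#'   [make_synthetic_catalog()].
#' @return A `synthetic_cohort` list: `metadata`, `taxonomic`,
#'   `genefamilies`, `metabolites`, `catalog`, `truth`.
#' @export
generate_cohort <- function(config, catalog = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(catalog)) catalog <- make_synthetic_catalog(config)
  md <- generate_metadata(config)
  tax <- generate_taxonomic(config, md)
  mtb <- generate_metabolites(config, md)
  tax_truth <- attr(tax, "truth")
  mtb_incr <- attr(mtb, "truth")$score_increment
  incr <- tax_truth$score_increment[md$subject_id]
  incr[is.na(incr)] <- 0
  m2 <- mtb_incr[md$subject_id]
  m2[is.na(m2)] <- 0
  md$srs2_tscore <- md$srs2_tscore + as.numeric(incr) + as.numeric(m2)
  gf <- generate_genefamilies(config, md, catalog)
  truth <- list(config = unclass(config),
                pseudocount_taxon = tax_truth$pseudocount,
                score_increment_species =
                  as.list(tax_truth$score_increment),
                score_increment_metabolite = as.list(mtb_incr))
  structure(list(metadata = md, taxonomic = tax, genefamilies = gf,
                 metabolites = mtb, catalog = catalog, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d samples (%d subjects), %d species, %d gene families\n",
    nrow(x$metadata), length(unique(x$metadata$subject_id)),
    ncol(x$taxonomic$values), ncol(x$genefamilies$values)))
  invisible(x)
}

#' Write a synthetic cohort to disk in the standard formats
#'
#' Writes the MetaPhlAn-style taxonomic table, HUMAnN-style gene-family
#' table, metadata CSV, metabolite TSV and a `truth.json` sidecar recording
#' every planted parameter.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("taxonomic.tsv", "genefamilies.tsv",
                            "metadata.csv", "metabolites.tsv", "truth.json"))
  write_taxonomic_profiles(cohort$taxonomic, paths[1])
  write_genefamily_profiles(cohort$genefamilies, paths[2])
  write_metadata(cohort$metadata, paths[3])
  utils::write.table(
    data.frame(sample_id = rownames(cohort$metabolites),
               cohort$metabolites, check.names = FALSE),
    paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths[5], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
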