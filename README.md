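# gutsea

Statistical pipeline for prospective **gut-microbiome → social-behavior**
analyses in birth cohorts. `gutsea` takes MetaPhlAn-style species profiles,
HUMAnN-style UniRef90 gene-family profiles (with per-taxon stratification),
sample covariates and Social Responsiveness Scale (SRS-2) T-scores, and
runs the analysis layer such studies report:

* **Feature-set enrichment (FSEA)** of neuroactive gene sets: Pearson
  correlations of each gene family (found in ≥ 4 subjects) with SRS-2
  scores or covariate-adjusted residuals, a Mann–Whitney U test of each
  set's correlations against all out-of-set correlations, and BH-FDR
  across sets (significance at q < 0.1). Per-taxon contributions to a
  set come from the stratified table.
* **Community structure**: Bray–Curtis dissimilarities with marginal-term
  PERMANOVA (`adonis2`-style R², pseudo-F, permutation p), plus Shannon /
  inverse-Simpson diversity regressions (score difference per SD of
  diversity).
* **Per-species screens**: abundance-as-outcome linear models with BH-FDR,
  reverse regressions in T-score points **per doubling** of relative
  abundance, sex-interaction models, and multiple imputation of missing
  covariates (chained equations, PMM) pooled by Rubin's rules.
* **Cross-cohort transfer**: a linear model trained in one cohort predicts
  scores in the other; evaluated by correlation, RMSE and MAE.
* **Metabolite regressions**: SRS-2 scores on log2 fecal metabolite
  concentrations, unadjusted and fully adjusted.
* A **seeded synthetic-cohort generator** that emulates the two-cohort
  study design (200 + 90 subjects, early/late stool samples, Table-1-style
  covariates with missingness, sparse compositional profiles, planted
  effects on the reported scales), so the whole pipeline is testable
  without restricted cohort data.

The enrichment statistic for a set *S* over per-family correlations *r* is

    U = Σ_{j∈S} #{k∉S : r_k < r_j} + ½·#ties

with exact two-sided p for moderate tie-free problems and a tie-corrected
normal approximation otherwise; `med` is the median in-set correlation.

## Worked example

```r
library(gutsea)

cfg    <- simulation_config(seed = 42)   # defaults = two-cohort study design
cohort <- generate_cohort(cfg)
cohort
#> synthetic_cohort: 580 samples (290 subjects), 100 species, 2000 gene families

md      <- cohort$metadata
early_A <- md$cohort == "A" & md$sample_age_window == "early"

## FSEA on the early window of the first cohort
gf  <- subset_samples(cohort$genefamilies, md$sample_id[early_A])
res <- run_fsea(gf, md[early_A, ], cohort$catalog,
                covariates = c("gestational_age", "sex", "breastfeeding"),
                measures = "score")
head(res[, c("set", "n_in", "U", "med", "p", "q", "significant")], 4)
#>                set n_in     U     med        p        q significant
#> 1 synthetic_set_01   46 64680  0.0653 3.43e-07 1.03e-05        TRUE
#> 2 synthetic_set_02   34 29027 -0.0313 1.88e-01 7.25e-01       FALSE
#> 3 synthetic_set_04   20 23418  0.0238 1.59e-01 7.25e-01       FALSE
#> 4 synthetic_set_07   42 45936  0.0150 1.93e-01 7.25e-01       FALSE
```

The generator plants a correlation of 0.15 between the score and the
families of `synthetic_set_01`; FSEA flags exactly that set (q ≪ 0.1, a
positive median in-set correlation), while the other sets stay null.

```r
## PERMANOVA: does the score explain community structure?
tax <- subset_samples(cohort$taxonomic, md$sample_id[early_A])
permanova_marginal(bray_curtis(tax), md[early_A, ],
                   c("srs2_tscore", "sex"), n_permutations = 999, seed = 1)
#>          term  df     SS      R2     F     p
#> 1 srs2_tscore   1  0.269 0.00335 0.667 0.911
#> 2         sex   1  0.528 0.00658 1.310 0.138
#> 3    Residual 197 79.359 0.99007    NA    NA
#> 4       Total 199 80.154 1.00000    NA    NA

## per-doubling effect of the planted species
fit <- reverse_regression(tax$values[, "species_001"], md[early_A, ],
                          pseudocount = cohort$truth$pseudocount_taxon)
fit[fit$term == "log2_abundance", ]
#>             term estimate     se ci_low ci_high        p   n
#> 2 log2_abundance    0.172 0.0386 0.0962   0.248 1.43e-05 200
```

The default cohort spreads the planted 0.41-per-doubling species effect
over the subject's two sample windows, so a single-window regression
recovers about half of it — clearly detected (p ≈ 1e-5), with full-size
recovery shown in the single-window simulations of the test suite. The
PERMANOVA here is null (no community-level structure is planted by
default): R² is small and p is large, as expected.

`run_pipeline(pipeline_config(...))` executes everything per cohort ×
age-window stratum and writes `permanova.tsv`, `diversity.tsv`,
`screen.tsv`, `screen_hits.tsv`, `fsea.tsv`, `transfer_eval.tsv`,
`metab.tsv` and a hashed `manifest.json`. A thin command-line wrapper is
in `inst/scripts/pipeline.R`.

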