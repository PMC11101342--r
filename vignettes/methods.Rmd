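---
title: "Methods: gene-set enrichment and association analysis of infant gut metagenomes against social-behavior scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutsea)
```

## The scientific setting

Prospective birth-cohort studies ask whether features of the early-life gut
microbiome — measured from shotgun metagenomes of infant stool — predict
later neurodevelopmental outcomes, here social behavior quantified by the
Social Responsiveness Scale, 2nd edition (SRS-2). SRS-2 total scores are
standardized T-scores (population mean 50, SD 10); higher values indicate
behavior more typical of autism spectrum disorder. The package implements
the statistical layer of such a study for two cohorts sampled in two age
windows (early, under 6 months; late, 6 months to 2 years), consuming
MetaPhlAn-style species profiles and HUMAnN-style UniRef90 gene-family
profiles with their `|`-delimited per-taxon stratification.

Five analysis families are provided:

1. **Community structure and diversity** — Bray–Curtis dissimilarities with
   marginal-term PERMANOVA, and linear regression of SRS-2 scores on
   z-standardized Shannon / inverse-Simpson diversity.
2. **Per-species screen** — abundance-as-outcome linear models
   (MaAsLin2-style) with BH-FDR, followed by reverse regressions reporting
   the score difference per doubling of relative abundance, and sex
   interactions.
3. **Feature-set enrichment (FSEA)** — the core procedure: per-gene-family
   Pearson correlations with the score (and with covariate-adjusted
   residuals), then a Mann–Whitney U test of each neuroactive gene set's
   correlations against all out-of-set correlations, with BH-FDR across
   sets.
4. **Cross-cohort transfer** — a linear model trained in one cohort
   predicting scores in the other, evaluated by correlation and error.
5. **Metabolite regressions** — SRS-2 scores on log2 relative
   concentrations of fecal metabolites, unadjusted and covariate-adjusted.

## The enrichment model

For gene family $j$ with relative abundance $x_{ij}$ in subject $i$ and
measure $m_i$ (raw score or residual), the correlation vector is the
Pearson coefficient $r_j = \mathrm{cor}(x_{\cdot j}, m)$, computed with
zeros kept as observed zeros. Families found in fewer than 4 subjects are
excluded — very rare families produce unstable correlations — as are
zero-variance families. For a set $S$ the statistic is

$$U = \sum_{j \in S} \#\{k \notin S : r_k < r_j\} + \tfrac12\,\#\text{ties},$$

with a two-sided p-value from the exact null distribution of $U$ when
$n_{in} n_{out} \le 10{,}000$ and the correlations are tie-free, and
otherwise from the tie-corrected normal approximation *without* continuity
correction (matching the behavior of the Julia HypothesisTests
implementation commonly used for this analysis; R's `wilcox.test` applies
the correction by default, which changes p-values in the third decimal at
these sample sizes). The reported `med` is the median in-set correlation;
a median-difference variant (in-set minus out-of-set) is available via
`med = "difference"` because the field's reports do not always state which
is meant. Significance is flagged at BH-FDR $q < 0.1$, applied across sets
within one measure and one cohort × age-window stratum; early and late
samples are never pooled.

The residual measure comes from `residualize()`: OLS residuals of the score
on the full covariate set (gestational age, child's sex, peripartum
antibiotics, delivery mode, exclusive breastfeeding at collection, maternal
smoking, maternal and paternal age, marital status, parity, maternal
education, child's age at assessment). Residuals are exactly orthogonal to
every covariate column, so enrichment against them cannot be driven by
those covariates.

Gene sets are defined as KEGG Ortholog collections and resolved to UniRef90
membership through a KO→UniRef90 mapping table (union over the set's KOs).
Unmapped KOs are counted per set rather than silently dropped, and a set
losing all members is flagged untestable. Per-taxon attribution of a set's
abundance uses the stratified rows: a taxon's share is its summed
stratified abundance over in-set families and samples divided by the
stratified in-set total.

## PERMANOVA

`permanova_marginal()` follows the `adonis2` marginal-test semantics the
field uses. Squared Bray–Curtis distances are Gower-centered into
$G$; for each term the marginal sum of squares is
$\mathrm{tr}(H_{full}G) - \mathrm{tr}(H_{-t}G)$ with $H$ the hat matrices
of the full design and the design without that term; $R^2$ divides by
$\mathrm{tr}(G)$ and the pseudo-F uses the residual mean square.
Significance uses free permutation of metadata rows — implemented as
conjugate permutation of $G$, which is algebraically identical and lets the
hat matrices be computed once — with the add-one estimator
$p = (1 + \#\{F^* \ge F\})/(1 + B)$ and a default of $B = 9999$. The p
resolution is therefore $1/(B+1)$. Rank-deficient designs error with the
collinear terms named; incomplete covariate rows must be imputed or
dropped upstream, by design. The one-term statistic is verified in the test
suite against both a literal-formula oracle (explicit loops) and
`vegan::adonis2`, and the permutation test's type-I error is checked by
null simulation.

## Associations, imputation, pooling

The species screen models
$\log_2(\text{relative abundance} + \text{pseudocount})$ as the outcome on
score plus covariates; the pseudocount is half the smallest nonzero value
of the table (a single table-level constant, so between-sample contrasts
are preserved). The default prevalence filter keeps features nonzero in at
least 10% of samples. Hits at $q < 0.1$ are re-fit in the reverse
direction — score on log2 abundance — so effects are reported in T-score
points per doubling, the field's unit. Sex interactions add a
sex × log2-abundance product term; the interaction p comes from that
coefficient's test, and per-sex estimates come from stratified fits (which
equal the full model refit on one sex, a property the tests assert).

Missing covariates are handled by a compact chained-equations imputer:
predictive mean matching for continuous covariates (OLS on all other
covariates, donor pool of the 5 nearest predictions) and logistic-score
matching for binary ones, 10 sweeps, 20 completed copies by default, each
on its own seeded stream. Downstream coefficients are pooled by Rubin's
rules: pooled $\beta$ is the mean; total variance is
$\bar W + (1 + 1/m)B$. With zero missingness the imputation path reduces
exactly to the complete-case path. Missingness is treated as MCAR in the
generator; the imputer itself is agnostic, but the recovery tests only
establish behavior under MCAR.

Confidence intervals throughout use the normal approximation
($\pm 1.96\,\mathrm{SE}$); at the study's sample sizes the difference from
t quantiles is negligible, and `ci = "t"` switches convention where it
matters.

## The synthetic cohort generator

Because the motivating cohort data are restricted, every analysis is
exercised on synthetic cohorts with the same statistical skeleton. The
defaults encode the study conditions: two cohorts of 200 and 90 subjects;
early and late samples per subject; covariates drawn from the published
population characteristics of a New England birth cohort (e.g. gestational
age 39.2 ± 1.7 weeks, maternal age 32.4 ± 4.2 years, 4.5% maternal smoking,
56% male) with the published missingness rates (e.g. 10.4% for
breastfeeding at collection); per-cohort SRS-2 intercepts 43.6 and 49.9
with residual SDs 4.8 and 8.5, matching the reported cohort means while the
instrument's normative scale is 50 (10).

Abundance tables are log-normal intensities (dispersion 2 for species, 1.5
for gene families on the natural-log scale) with Bernoulli zeroing
(expected zero fraction 0.6 for species, 0.3 for gene families) followed by
total-sum scaling — sparse and compositional like real profiles, but with
no phylogenetic correlation, no strain structure, and independent samples
within subject. Passing tests therefore demonstrate correctness of the
statistical machinery under realistic marginal structure, not robustness to
the dependence patterns of real microbiomes.

Planted truths use the scales the analyses report, so recovery is direct:

* **Species and metabolite effects** are T-score points per doubling,
  added to the score as $\beta(\log_2(x + pc) - \overline{\log_2(x+pc)})$
  (centered, so planting moves slopes, not the score's marginal mean).
  Defaults are 0.41 for one species and 0.86 for butyrate — effect sizes at
  the magnitude the motivating analyses report.
* **Set enrichment** plants a target correlation $\delta$: each in-set
  family's log abundance is $\delta z(\text{score}) +
  \sqrt{1-\delta^2}\,\varepsilon$, giving expected Pearson correlation
  exactly $\delta$ on the log scale before sparsification (the
  exponentiation, zeroing and renormalization attenuate the realized
  abundance-scale correlation, which is what the enrichment test sees —
  the power checks account for this by testing ranks, not magnitudes).
* **Confounding** runs formula feeding → higher butyrate (+1.5 doublings)
  alongside a direct breastfeeding effect on the score (−2 points), which
  reproduces the attenuation-on-adjustment pattern.

Generation is fully deterministic given config + seed; each generator runs
on its own seed offset, and the `truth` record (also written as
`truth.json`) suffices to compute every planted estimand. Score assembly is
ordered: base score (intercept + covariate effects + noise), then species
and metabolite contributions, and only then gene families, which need the
final score. Covariate missingness is masked *after* the score is formed,
so masked values still acted on the outcome, as in a real cohort.

## Numerical and design choices

* Shannon diversity uses the natural log; the inverse Simpson index is
  $1/\sum p_i^2$. An all-zero sample has undefined diversity (`NA` with a
  warning) and zero distance to another all-zero sample (with a warning).
* Percent vs proportion profiles are auto-detected (any sample column
  summing above 1.5 is percent) since MetaPhlAn emits percentages and
  synthetic fixtures emit proportions.
* `UNMAPPED`/`UNGROUPED` rows are excluded from the feature set but kept in
  the normalization denominator by default, so gene-family relative
  abundances refer to the whole community.
* Stratified gene-family tables are treated as the source of per-taxon
  contributions (stratification is a property of HUMAnN-style functional
  output; species-profile tables do not carry it).
* Species matching across cohorts is exact string equality after stripping
  rank prefixes; no fuzzy matching.
* Age windows are half-open: early $[0, 6)$ months, late $[6, 24]$ months.
* Subject identifiers must be unique within cohort × window (a subject
  legitimately appears in both windows).
* Ties in the enrichment statistic get the ½-tie convention in $U$ and the
  tie-corrected variance in the normal approximation; taxon-contribution
  ties in share are broken lexicographically.
* Transfer models use shared features (prevalence ≥ 0.1 in both cohorts)
  on the log2 scale; when predictors reach the sample count the fit falls
  back to seeded cross-validated ridge regression, a pragmatic extension
  for stress tests rather than a default path.

## Problem sizes used by the checks

The test-suite and acceptance-script simulations use deliberately modest
sizes chosen to estimate each property stably: 200 null communities
(n = 60, 40 species, 999 permutations) for PERMANOVA calibration; 50 (test
suite) or 30 (script) seeds for enrichment power at $\delta = 0.15$ with 50
of 2000 families and 100 subjects; 100–200 replicates for CI coverage of
the planted per-doubling effects; and an end-to-end determinism run at the
full two-cohort scale with 500 gene families and 199 permutations. These
sizes are the package's own verification design; the underlying functions
default to field-standard settings (9999 permutations, 2000 families).

## Known limitations

* Pearson correlations on relative abundances are sensitive to
  compositional closure and heavy tails; the enrichment test uses only
  their ranks, which softens but does not remove this.
* The generator's MCAR missingness cannot probe selection bias, one of the
  motivations for imputation in real cohorts.
* No repeated-measures modeling: early and late windows are analyzed
  separately, never jointly with random effects.
* The imputer is a compact PMM/logistic-matching scheme, not a full
  chained-equations framework with model diagnostics.
* Alternative beta-diversity metrics (UniFrac, Aitchison), ordination, and
  dispersion tests are out of scope.
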