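---
title: "Two-stage gene-environment interaction discovery via variance-QTL screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage gene-environment interaction discovery via variance-QTL screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vqtlewis)
```

## The model

A gene-environment interaction (GEI) on a quantitative trait is the
coefficient `beta_ge` in

```
y = beta_g * g + beta_e * e + beta_ge * (g * e) + eps,   eps ~ N(0, sigma^2)
```

where `g` is an additively coded genotype (0/1/2 alternate-allele copies)
and `e` an exposure. When `beta_ge != 0` and `e` is not observed, the
genotype classes differ in variance: for a single interacting exposure
with variance `s_e^2`,

```
Var(y | g = k) = (beta_e + beta_ge * k)^2 * s_e^2 + sigma^2 .
```

This is the footprint the two-stage design exploits. Stage one scans the
genome for variance heterogeneity — cheap, exposure-free — and stage two
tests only the prioritized variant-biomarker pairs against the full
exposure panel, paying the multiple-testing price for a few hundred pairs
instead of millions of variants.

### Stage one: the median-based Levene test

`levene_median_test()` replaces each observation by its absolute
deviation from the *median* of its genotype class and runs a one-way
ANOVA on those deviations. Median centering (the Brown-Forsythe variant)
is what makes the test usable on log-scale biomarkers: mean-centered
Levene is badly anticonservative under skew, while the median version
keeps close-to-nominal type-I error, which the test suite verifies
empirically (2,000 null replicates must stay inside the 99% binomial band
around 0.05).

The test is direction-free, so `vqtl_direction_and_effect()` recovers a
sign from the regression of the deviations on allele count and converts
the (two-sided) p-value into a per-allele effect and standard error via

```
z  = dir * qnorm(1 - p/2)
b  = z / sqrt(2 p (1-p) (n + z^2)),   SE = 1 / sqrt(2 p (1-p) (n + z^2))
```

with `p` the minor allele frequency. `b/SE = z` holds identically, which
the suite asserts to 1e-12; the back-transformation exists so that
variance results can flow through the same summary-statistic files and
meta-analysis machinery as ordinary GWAS estimates.

Numerical choices: p-values are floored at 1e-300 before inversion so `z`
stays finite; a direction tie (slope exactly 0) gives direction 0 and
effect 0; genotype classes with fewer than `min_class_count = 2`
observations are dropped before the class count `k` is formed (with two
observations per class the within-class deviations are constant and the F
ratio diverges — the implementation reports `F = Inf, p = 0` in that
case and errors only when the deviations are identically zero).

### Meta-analysis across ancestry strata

Strata are analyzed separately and combined on a common effect allele
(`align_alleles()` flips swapped reports and drops irreconcilable ones).
Variance results carry no native effect size, so the vQTL meta-analysis
uses Stouffer's sample-size-weighted z combination
(`z_meta = sum(sqrt(n_i) z_i)/sqrt(sum n_i)`); mean-effect and
interaction estimates use inverse-variance weighting
(`w_i = 1/se_i^2`). Cochran's Q is computed and reported for IVW but
never used to filter. Variants present in a single stratum are retained —
ancestry-specific frequency differences are a feature of multi-ancestry
panels, not an error — and the per-stratum direction string (`"++-?"`)
records who contributed.

### Pruning and locus bookkeeping

`distance_prune()` implements greedy distance-based clumping: take the
most significant remaining variant, absorb everything within ±500 kb on
its chromosome, repeat. Ties in p break lexicographically by (chromosome,
position, id), making output independent of row order; the window is
center-to-point and boundary-inclusive. No LD information enters — by
design, since per-ancestry LD reference panels would otherwise be needed.
`cross_clump()` re-applies the same rule at ±1 Mb across stacked index
sets to group loci across biomarkers and analysis kinds, and
`classify_loci()` labels vQTL loci as shared with, or exclusive of,
mean-effect loci.

### Stage two: robust interaction tests

`gei_test()` fits `y ~ g + e + g:e` by OLS and takes the interaction SE
from the heteroskedasticity-consistent sandwich estimator
(`sandwich::vcovHC`, HC0 by default, HC1/HC3 selectable). Robust errors
are not a refinement here but a requirement: under a true interaction the
residual variance is genotype-dependent by construction, and classical
SEs are wrong even asymptotically. HC0 was chosen as the default because
it is the baseline flavor of the sandwich family and the difference from
HC1/HC3 is O(1/n) at biobank-scale n; the test suite checks the estimator
against the explicit matrix formula
`(X'X)^-1 X' diag(r^2) X (X'X)^-1` to 1e-10 and verifies calibrated
type-I error under heteroskedastic nulls. No covariates enter the primary
model because phenotypes are residualized upstream; an `extra_covariates`
hook supports adjusted variants of the analysis. A perfect fit (zero
residuals) degenerates the sandwich; it is flagged (`exact_fit`) and the
p-value floored rather than returned as NaN.

Multiplicity control uses `alpha / n_pairs / n_effective_exposures`,
where the effective count `(sum lambda)^2 / sum lambda^2` over the
eigenvalues of the exposure correlation matrix (`effective_tests()`)
recognizes that a dense exposome panel carries far fewer independent
tests than columns. The same formula dimensioned stage one (effective
biomarkers times genome-wide variants).

### Conditional scan

Correlated exposures produce blocks of significant interactions that are
one signal, not many. `conditional_scan()` counts independent signals:
select the most significant exposure, then re-test the remainder while
conditioning on each selected exposure `s` — adding *both* `s` and
`g:s`. Conditioning only on the interaction term, with the main effect
omitted, would leave the conditional null misspecified whenever the
selected exposure also has a main effect, so both terms enter; this is a
deliberate design choice. Near-duplicates (|r| > 0.99 with a selected
exposure) are skipped rather than fitted into collinearity. The stop rule
(Bonferroni-strict or nominal 0.05) is the caller's choice and reported
alongside the chain.

### Enrichment statistics

`enrichment_chisq()` is a df-1 chi-square test of independence with Yates
correction, with the p-value computed in log space
(`pchisq(log.p = TRUE)`) because triplet-level enrichment comparisons
produce p-values far below double underflow; such values are carried as
`log10_p` and `p_value` is reported as 0.

## Pre-processing

Biomarkers (`preprocess_biomarker()`): statin users' raw values divided
by the biomarker-specific adjustment factor (total cholesterol 0.749,
LDL-C 0.684, ApoB 0.719 — taken as given constants, not estimated); then
natural log; OLS residualization on the user-supplied covariate matrix;
masking of residuals beyond 5 SD from the residual mean (one pass, no
iteration); z-scoring of the survivors. The order matters and is fixed:
masking precedes the final standardization, and the statin division acts
on the measured scale so that the log sees adjusted concentrations.

Exposures (`prepare_exposures()`): continuous and integer columns get the
rank-based inverse normal transformation (Blom offset 3/8 — the common
GWAS convention; ties get average ranks); two-level categoricals become
0/1 with the *majority* level as 0; ordered categoricals with more levels
become 0..k-1 codes; multiple-choice columns expand to per-level
indicators. Columns with fewer non-missing values than a tenth of the
sample (a fixture-scaled default; override `min_nonmissing` for real
data), a single observed level, or a rarest binary level under
`min_minor_count = 10` are dropped and listed with reasons.

Genotypes: imputed dosages are hard-called within 0.1 of an integer
(`hard_call()`, boundary inclusive with an epsilon guard against
floating-point noise) and filtered at MAF > 0.005 by default, both
configurable. Multi-allelic VCF records are rejected rather than split.
Missing genotypes are excluded per test (complete-case), never imputed.

## The synthetic-data generator

`make_study()` emulates the features of biobank data the pipeline's
statistics actually touch: Hardy-Weinberg hard-call genotypes across
ancestry strata of very different sizes, block-correlated mixed-type
exposures (a "body-mass-like" and a "body-fat-like" block at within-block
correlation 0.8, echoing real anthropometric panels, plus independent
lifestyle columns with some median-dichotomized), and phenotypes from the
linear interaction model above, optionally exponentiated to a skewed raw
scale to exercise the log/INT path. Ground truth (all nonzero effects) is
retained in the returned object and the `truth.json` written next to the
PLINK fileset.

What it deliberately does *not* emulate: linkage disequilibrium (variants
are independent; pruning logic is tested on positional fixtures),
imputation quality, genuinely non-Gaussian exposure distributions,
population stratification, or relatedness. Passing tests therefore
demonstrate correctness of the statistical machinery under the generating
model, not robustness to every artifact of real cohort data.

## Study conditions used by the tests and the acceptance script

These sizes were chosen once, by design-phase power analysis, as the
smallest configurations where the qualitative phenomena are clearly
resolved on one CPU in minutes:

- Type-I error: 2,000 null replicates at n = 2,000, MAF 0.3; acceptance
  band is the 99% binomial band [0.037, 0.063].
- Estimator recovery: 500 replicates at n = 10,000, `beta_ge = 0.1`,
  MAF 0.3; bias within 2 Monte-Carlo SEs, 95% CI coverage in
  [0.93, 0.97].
- Power grid: `beta_ge` in {0, 0.05, 0.1, 0.2} at n = 10,000 with
  `beta_e = 0.3`, 200 replicates per point; detection at nominal 0.05.
  The exposure main effect matters: with `beta_e = 0`, the class
  variances differ only by `beta_ge^2 k^2`, and desk-scale power would
  collapse at the small grid values.
- Qualitative interaction (the vQTL-without-main-effect pattern): 50
  replicates at n = 50,000, MAF 0.25, `e ~ N(1, 1)`,
  `beta_ge = 0.25`, `beta_g = -0.25`, so the marginal slope
  `beta_g + beta_ge * E[e]` is exactly zero; the median Levene p falls
  below 1e-6 while the median mean-effect p stays above 0.01. This is
  the construction in which a variant "cancels out" of a standard GWAS
  while carrying a strong interaction.
- Two-stage enrichment: 20 replicate studies at n = 5,000 with 60
  variants (8 carrying both a main effect 0.15 and an interaction 0.3
  with one exposure of a 10-exposure panel, 40 main-effect-only, 12
  null), stage-1 threshold 1e-4 in both arms and a shared stage-2
  Bonferroni threshold. The fraction of prioritized variants with a
  significant interaction must be strictly higher in the vQTL arm than
  the mean-effect arm in at least 18/20 studies.

The interaction effect sizes themselves are arbitrary in the sense that
no empirical effect-size distribution is available to match; they are
fixed at values giving adequate desk-scale power and documented here so
that they are not mistaken for estimates.

## Known limitations

- Mean-effect and interaction models are plain OLS: no mixed models, so
  samples must be unrelated; no dominance or non-additive codings.
- Distance-based pruning can merge truly distinct signals in gene-dense
  regions and cannot split signals in LD across a window boundary.
- The conditional scan is greedy forward selection; it counts signals, it
  does not perform model selection with guarantees.
- Stouffer weights use raw stratum sample sizes, not effective sizes.
- BGEN input and phased haplotypes are unsupported; multi-allelics must
  be split upstream.

## Interfaces

Everything is a function over data frames/tibbles (genotypes travel in a
light matrix container); `tidy()`/`glance()` methods cover the fitted
objects, and `plot_scan()`, `plot_stratified_means()` and
`autoplot()` (exposure PCA) give the standard displays. File formats:
PLINK1 BED/BIM/FAM and VCF in, tab-delimited summary statistics
(`CHR POS ID A1 A2 AF N STAT BETA SE DIR P KIND STRATUM`) in and out,
lossless to full double precision.
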