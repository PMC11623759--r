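---
title: "Microbial clique analysis: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbial clique analysis: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Epidemiological microbiome studies usually relate a health outcome to single
taxa or to whole-community summaries. Between those extremes sit *microbial
cliques*: small sets of taxa whose joint presence carries a signal that no
single member carries on its own. This package implements a two-stage
Microbiome Co-occurrence Analysis (MiCA) for a cohort design in which the
outcome is a risk-of-cognitive-impairment (RCI) score derived from a
three-word recall test, the exposure is the gut microbiome profiled by 16S
amplicon sequencing, and a binary food-insecurity indicator stratifies the
cohort so that effect modification can be assessed.

The outcome enters models as `rci = log(1 + (3 - minicog))`: the recall count
(0-3, higher = better) is inverted so larger values mean greater risk, and
log-transformed to tame the skew of the inverted score. The `+1` offset is
forced by perfect recall inverting to zero; `log(4 - score)` is the minimal
such convention, and `invert_outcome()` restores the integer score exactly.

## Stage 1: repeated-holdout signed iterative random forests

Stage 1 (`repeated_holdout_discovery()`) hunts for taxon sets that predict
higher RCI. Its unit of evidence is a *signed decision path*: every
root-to-leaf path of a regression tree conditions on some taxa being above
("high") or below ("low") split thresholds; for zero-inflated relative
abundances the first split of a taxon is effectively presence/absence.

One *repeat* consists of:

1. a 60/40 train/test partition;
2. an iterated random forest on the training part: weights start uniform,
   and each iteration re-samples candidate split variables proportionally to
   the previous forest's impurity importances (`iterate_importance()`,
   implemented over `ranger`'s weighted split selection);
3. a holdout screen — if the final training forest has non-positive R² on
   the 40% holdout, the repeat contributes nothing (under a pure-noise
   outcome almost every repeat is screened out, which is what keeps the
   null behaviour silent);
4. for each bootstrap resample of the training part: the reweighting loop,
   a weighted forest, signed decision-path itemsets, and random
   intersection trees (RIT) over those itemsets;
5. a holdout *synergy screen* on every candidate set the RIT stage emits:
   the candidate's presence-count indicator must correlate positively with
   the held-out outcome at least as strongly as each of its single members.

A candidate's *stability* is the fraction of repeats in which it was
recovered by at least one bootstrap. `select_cliques()` keeps candidates at
or above `min_stability` (default 0.5) and merges retained candidates that
share a taxon into one connected component — the "closed-loop network"
reported as a single clique.

Several of these choices deserve their reasoning spelled out:

* **High-side orientation.** Before the intersection stage each path is
  reduced to its high-side items, each surviving path counting once. In
  zero-inflated tables most leaf mass sits on paths that condition on taxa
  being *absent*; intersecting raw count-weighted paths therefore surfaces
  co-absence patterns, which are not presence cliques. `signed_itemsets()`
  itself still reports both sides with leaf-occupancy weights, so the raw
  itemset representation remains available.
* **The synergy screen.** Weak but real cliques are easily outranked by
  pairs that hitch the clique's strongest member to a noise taxon: such a
  pair inherits the strong member's stability. Requiring the set to
  out-predict its best single member out of sample is the operational
  definition of a synergistic combination, and it is evaluated on data the
  forest never saw. Without it, simulation shows the top-ranked pair usually
  contains exactly one planted taxon.
* **RIT node recording.** Every intersection node of size ≥ 2 is collected,
  not only sets surviving to full depth. With realistic signal strengths a
  true pair appears in a few percent of paths; demanding survival through
  five consecutive intersections (probability ∝ f⁶) would return nothing at
  desk scale. Prevalences are always reported as exact containment fractions
  over all itemsets, so deeper survivors gain nothing but sampling
  preference. A child node never re-draws its parent's own itemset, so every
  intersection involves distinct draws.
* **Forest shape.** 100 trees, depth ≤ 5, minimum leaf 5, `mtry = √p`, 3
  reweighting iterations (defaults from the iterative-random-forest
  literature; the scaled-down preset `fast_discovery_config()` uses 50
  repeats × 20 bootstraps with 60-tree forests and is what the test suite
  exercises). Stability is counted over all repeats, screened or not, so
  screening can only lower stability, never inflate it.

## Stage 2: clique-indicator inference

For a clique of k taxa the per-sample indicator counts its present members
(0..k, presence = relative abundance > 0); a sample *harbors* the clique if
the indicator is ≥ 1. The indicator enters a covariate-adjusted linear model
of RCI as a single linear term, and inference uses a permutation test: the
outcome vector is permuted wholesale 10⁵ times (configurable), the |t| of
the indicator coefficient is recomputed each time, and
`p = (1 + #{|t*| ≥ |t|}) / (1 + B)` with add-one smoothing so p is never
zero. The |t| statistic is pivot-like and more robust than the raw
coefficient under heteroscedastic noise; the outcome is permuted directly
(not residualized) because the design intends no reliance on an estimated
null model. Exhaustive enumeration over all n! orderings replaces sampling
for tiny n, and ties between the observed and permuted statistics are
counted as exceedances (a relative tolerance of 1e-8 absorbs the different
BLAS batching of the two computations; residual sums below 1e-20 of the
outcome's sum of squares are treated as saturated fits).

Stratified analysis fits the same model separately in the food-secure and
food-insecure strata (`stratified_effects()`), and `cross_stratum_validate()`
re-tests a clique discovered in one stratum on the samples of the other.
Models adjust for age, race/ethnicity (non-Hispanic-White indicator), BMI,
gender, pet ownership, smoking history, dietary fiber, and antibiotic use;
95% CIs are normal-theory (`beta ± 1.96·se`).

## Preparation conventions

* Relative abundance per sample; taxa kept only if present in strictly more
  than 5% of samples; retained abundances are *not* rescaled afterwards.
* Shannon diversity `H = −Σ p log p` (natural log) over non-zero entries,
  delegated to `vegan::diversity()`.
* Per-taxon association scans quartile-encode each taxon (type-7 sample
  quantiles, ties to the lower quartile) so coefficients are comparable
  across taxa. When one repeated value holds more than 25% of the vector —
  structural zeros, typically — that mass is coded 1 and the remaining
  values are split by their own quartiles; applying the mass rule
  recursively instead would degenerate (any short remainder re-triggers it
  and everything codes 1). A constant taxon codes all-1 with a warning.
* Benjamini–Hochberg FDR within each scan.
* Covariate missingness (< 2% by design) is imputed once by predictive mean
  matching: linear predictions from the other covariates, donor drawn
  uniformly from the 5 nearest-prediction complete cases, so imputed values
  always come from the observed support. Samples missing the stratum or the
  cognitive score are dropped, not imputed.
* Sensitivity: `subclass_balance()` scores exposure (harboring ≥ 1) on the
  covariates with a linear model, cuts the score into quintile subclasses,
  and reports standardized mean differences raw and subclass-weighted, as a
  love-plot table.

## The synthetic cohort generator

Real cohort data cannot ship with the package, so `generate_cohort()` draws
cohorts with known ground truth at the study's conditions: n = 360 with
18.9% food-insecure; two planted cliques with per-stratum indicator effects
(0.05 secure / 0.29 insecure for a 2-taxon clique; 0.10 / 0.07 for a 4-taxon
clique); a direct stratum effect of 0.06; covariates matched to the cohort's
descriptive table (age 61.5 (13.4), BMI 31.0 (7.4), fiber 19.1 (10.0)
truncated at zero, binary frequencies likewise).

Abundances are per-sample Dirichlet draws whose concentrations decay with
taxon rank (`j^-0.6`, total concentration 250), with each taxon structurally
zeroed at probability `sparsity` (default 0.80) and the composition
renormalised. The defaults were fixed once against the cohort's printed
descriptive statistics: the concentration scale puts mean per-sample Shannon
diversity near 3.3, and the planted cliques' per-taxon presence
probabilities (0.134 for the 2-taxon, 0.0973 for the 4-taxon clique) put the
fraction of samples harboring them near 25% and 34%.

The latent risk adds stratum, clique, covariate, and Gaussian noise terms
and is then discretised to the 0-3 recall score by fixed population
quantiles (0.55 / 0.87 / 0.98), giving score frequencies (0.55, 0.32, 0.11,
0.02) with mean 2.40 and SD 0.76. Two facts about this discretisation
matter. First, the cut-points are a modeling choice — the score's marginal
distribution beyond its mean and SD is not an anchored quantity. Second,
`noise_sd = 0.4` was chosen (on a 100k-sample grid) so that the composite
map latent → score → `rci` is locally affine with slope ≈ 1: stratified
regressions of the transformed score on a planted clique's indicator then
recover the configured effects without systematic attenuation or
amplification, which is what makes parameter-recovery testing meaningful.

What the generator does *not* emulate: phylogenetic correlation among taxa,
read-depth variation and rarefaction artefacts, covariate-dependent
(non-MCAR) missingness, and any dependence of the microbiome on the
covariates. Passing tests therefore certify the statistical machinery under
a clean compositional model, not robustness to those real-data features.

## Problem sizes used by the tests

The suite exercises the scaled-down discovery preset (50 repeats × 20
bootstraps, 100 taxa, n = 360), 2000 null replicates of 1000 permutations
each for type-I-error calibration, 20 generator seeds for stratified
parameter recovery, and 10 + 10 master seeds for planted/null discovery.
The planted discovery benchmark gives the pair's presence-count indicator a
standardized effect of 0.3 (0.3 outcome-SD per indicator-SD, members present
in half the samples) — the same standardized magnitude as the strongest
clique effect the stratified analysis is designed to detect. Weaker
plantings are not reliably rankable by *any* procedure at this scale: the
largest spurious pair association among ~5000 candidate pairs exceeds such
signals in most realizations, a bound one can check with an exhaustive scan.

## Known limitations

* Discovery power at stratum sizes below ~100 samples is modest; the
  holdout screens trade recall for a very low false-discovery surface.
* The permutation test assumes exchangeability of outcomes under the null;
  covariate-outcome dependence is handled by adjustment, not by restricted
  permutation.
* Quartile encoding within stratified scans is recomputed on each analysis
  set (pooled vs per-stratum quartiles is a genuine design fork; per-set
  recomputation keeps each model self-contained).
* Single imputation is appropriate for the sub-2% missingness the design
  assumes; no between-imputation variance is propagated.
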