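# mica

Microbial clique discovery and effect-modification inference for
microbiome cohorts.

## The problem

Single-taxon association scans miss signals carried jointly by small groups
of gut microbes. `mica` implements a two-stage Microbiome Co-occurrence
Analysis for epidemiological cohorts in which the outcome is a risk of
cognitive impairment (RCI) score derived from a three-word recall test
(`rci = log(1 + (3 − minicog))`, higher = greater risk), the exposure is a
16S ASV relative-abundance table, and a binary food-insecurity indicator
stratifies the cohort so that effect modification can be assessed. It is
aimed at biostatisticians and microbiome epidemiologists who want the whole
pipeline — preparation, per-taxon scans, clique discovery, permutation
inference, sensitivity checks — reproducible from one seed.

**Stage 1 — discovery (rh-SiRF).** A repeated-holdout signed iterative
Random Forest: for each of many 60/40 train/test partitions, iteratively
feature-reweighted regression forests are grown on bootstrap resamples of
the training part; signed decision paths (taxon *high*/*low* per split) are
intersected by random intersection trees to surface recurring presence
combinations; each repeat's holdout screens both the forest (out-of-sample
R² > 0) and every candidate (its presence-count indicator must out-predict
each single member on held-out data). A candidate's *stability* is the
fraction of repeats in which it recurs; overlapping candidates above the
stability threshold merge into the final cliques.

**Stage 2 — inference.** For a clique of k taxa, the indicator
I ∈ {0..k} counts present members per sample. The covariate-adjusted model

    rci ~ β·I + age + race + BMI + gender + pets + smoking + fiber + antibiotics

is fit per stratum, with p-values from permuting the outcome 10⁵ times
(add-one smoothed, statistic |t| of β), plus cross-stratum validation and
propensity-subclass covariate-balance diagnostics (love plots). A
synthetic-cohort generator with planted cliques and known ground truth makes
every stage testable end to end.

## Worked example

```r
library(mica)

coh  <- generate_cohort(cohort_config(seed = 20))   # n = 360 synthetic cohort
meta <- coh$metadata
covs <- c("age","bmi","fiber_g","gender_female","race_white_nh",
          "pet_owner","ever_smoker","antibiotics_year")
meta[covs] <- pmm_impute(meta[covs], seed = 2)       # fill sparse missingness

# stage-2 stratified inference for the planted 2-taxon clique
stratified_effects(coh$table, meta, coh$truth$cliques[[1]],
                   n_permutations = 1e4, seed = 3)
#> Clique {ASV0001, ASV0002}
#>    stratum   beta   ci_low ci_high  p_robust   n n_harboring prevalence
#> 1   secure 0.1073 0.001064  0.2135 5.099e-02 290          70     0.2414
#> 2 insecure 0.5089 0.310335  0.7074 9.999e-05  70          17     0.2429
```

This cohort was generated with per-stratum true clique effects 0.05
(food-secure) and 0.29 (food-insecure) and ~25% of samples harboring the
clique: the fitted stratum betas bracket their truths within sampling error
(n = 70 in the insecure stratum, so the realized 0.51 sits within 3 SE of
0.29), the permutation p in the insecure stratum is at its lower bound for
10⁴ permutations, and the harboring prevalences land on the planted 25%.
The stronger-insecure / weaker-secure ordering — the effect-modification
signature the pipeline is built to detect — is recovered.

Stage-1 discovery and the full pipeline run the same way:

```r
cand <- repeated_holdout_discovery(coh$table, meta$rci,
                                   fast_discovery_config(seed = 7))
cliques <- select_cliques(cand, min_stability = 0.5)

report <- run_pipeline(run_config(coh$table, coh$metadata,
                                  output_dir = "out", seed = 42))
```

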