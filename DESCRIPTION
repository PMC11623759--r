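Package: mica
Title: Microbial Clique Discovery and Effect-Modification Inference for
    Microbiome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage Microbiome Co-occurrence Analysis (MiCA) for
    epidemiological cohorts: stage one discovers small sets of co-occurring
    taxa ("microbial cliques") predictive of a health outcome using a
    repeated-holdout signed-iterative Random Forest (rh-SiRF) with random
    intersection trees; stage two estimates covariate-adjusted associations
    between clique-presence indicators and the outcome with permutation-based
    p-values, stratified to assess effect modification. Includes feature-table
    preparation (relative abundance, prevalence filtering, Shannon diversity,
    quartile encoding), per-taxon adjusted association scans with FDR
    correction, predictive-mean-matching imputation, propensity-subclass
    covariate-balance diagnostics, and a synthetic-cohort generator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    ranger,
    stats,
    utils,
    vegan,
    withr
Suggests:
    biomformat,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
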