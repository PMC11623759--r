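# Shared fixtures, built in code at test time.

small_cohort <- function(seed = 1, n = 120, n_taxa = 40, ...) {
  generate_cohort(cohort_config(
    n_samples = n, n_taxa = n_taxa, seed = seed,
    planted_cliques = list(
      list(taxa = 1:2, effects = c(secure = 0.05, insecure = 0.29),
           presence = 0.134),
      list(taxa = 3:6, effects = c(secure = 0.10, insecure = 0.07),
           presence = 0.0973)),
    ...))
}

# Metadata frame reconstructed from a 2x2 of printed counts:
# rows secure/insecure, cols yes/no.
meta_from_2x2 <- function(counts, var) {
  fi <- rep(c(0, 1), times = rowSums(counts))
  x <- c(rep(c(1, 0), times = counts[1, ]), rep(c(1, 0), times = counts[2, ]))
  out <- data.frame(food_insecure = fi)
  out[[var]] <- x
  out
}

# Independent permutation enumerator (insertion construction, distinct from
# the package's recursive-prefix construction).
enum_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in enum_perms(n - 1)) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# Discovery fixture: planted 2-taxon clique among 100 taxa, n = 360, single
# stratum. The presence-count indicator of the pair carries a standardized
# effect of 0.3 (0.3 outcome-SD per indicator-SD; members present in half
# the samples, so the per-member jump is 0.3/sqrt(2 * 0.25)).
discovery_fixture <- function(seed, null = FALSE) {
  cc <- cohort_config(
    n_samples = 360, n_taxa = 100, p_food_insecure = 0, sparsity = 0.8,
    planted_cliques = list(list(taxa = 1:2,
                                effects = c(secure = 0, insecure = 0),
                                presence = 0.5)),
    noise_sd = 0.4, missing_rate = 0, seed = seed)
  coh <- generate_cohort(cc)
  X <- coh$table$values
  ind <- (X[, 1] > 0) + (X[, 2] > 0)
  y <- withr::with_seed(seed + 1000,
    if (null) rnorm(360) else (0.3 / sqrt(0.5)) * ind + rnorm(360))
  list(X = X, y = y, pair_key = "ASV0001:high,ASV0002:high")
}
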