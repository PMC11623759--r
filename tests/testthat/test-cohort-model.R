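test_that("generation is deterministic under a fixed seed", {
  a <- small_cohort(seed = 7)
  b <- small_cohort(seed = 7)
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$metadata, b$metadata)
  c <- small_cohort(seed = 8)
  expect_false(identical(a$table$values, c$table$values))
})

test_that("abundance rows are compositions and presence is controlled", {
  coh <- small_cohort(seed = 3)
  expect_true(all(coh$table$values >= 0))
  expect_equal(unname(rowSums(coh$table$values)), rep(1, 120),
               tolerance = 1e-12)
  expect_true(all(coh$metadata$minicog %in% 0:3))
  expect_equal(coh$metadata$rci, transform_outcome(coh$metadata$minicog))
})

test_that("stratum proportion converges to p_food_insecure", {
  coh <- generate_cohort(cohort_config(
    n_samples = 100000L, n_taxa = 8L, p_food_insecure = 0.189,
    planted_cliques = list(list(taxa = 1:2,
                                effects = c(secure = 0, insecure = 0))),
    seed = 21))
  p_hat <- mean(coh$metadata$food_insecure)
  se <- sqrt(0.189 * 0.811 / 100000)
  expect_lt(abs(p_hat - 0.189), 3 * se)
})

test_that("food-insecure count at the cohort's size matches its binomial mean", {
  coh <- generate_cohort(cohort_config(seed = 5))
  count <- sum(coh$metadata$food_insecure)
  sd <- sqrt(360 * 0.189 * 0.811)
  expect_lt(abs(count - 360 * 0.189), 3 * sd)
})

test_that("noise-free latent outcome is affine in the clique indicator within stratum", {
  zero_cov <- c(age = 0, bmi = 0, fiber_g = 0, gender_female = 0,
                race_white_nh = 0, pet_owner = 0, ever_smoker = 0,
                antibiotics_year = 0)
  coh <- generate_cohort(cohort_config(
    n_samples = 200, n_taxa = 20,
    planted_cliques = list(list(taxa = 1:2,
                                effects = c(secure = 0.05, insecure = 0.29),
                                presence = 0.3)),
    covariate_effects = zero_cov, noise_sd = 0, seed = 13))
  ind <- coh$truth$indicators[[1]]
  for (s in 0:1) {
    sel <- coh$metadata$food_insecure == s
    fit <- lm(coh$truth$latent[sel] ~ ind[sel])
    expect_lt(max(abs(residuals(fit))), 1e-10)
  }
})

test_that("null model with zero effects and zero noise gives a constant latent", {
  zero_cov <- c(age = 0, bmi = 0, fiber_g = 0, gender_female = 0,
                race_white_nh = 0, pet_owner = 0, ever_smoker = 0,
                antibiotics_year = 0)
  coh <- generate_cohort(cohort_config(
    n_samples = 50, n_taxa = 10,
    planted_cliques = list(list(taxa = 1:2,
                                effects = c(secure = 0, insecure = 0))),
    beta_food_insecurity = 0, covariate_effects = zero_cov,
    noise_sd = 0, seed = 2))
  expect_equal(var(coh$truth$latent), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(p_food_insecure = 1.2), "probability")
  expect_error(cohort_config(n_samples = 0), "integer")
  expect_error(cohort_config(noise_sd = -1), "non-negative")
  expect_error(cohort_config(
    n_taxa = 4,
    planted_cliques = list(list(taxa = 3:6,
                                effects = c(secure = 0, insecure = 0)))),
    "indices")
})

test_that("recovery report computes Jaccard overlap against planted truth", {
  coh <- generate_cohort(cohort_config(
    n_samples = 30, n_taxa = 10,
    planted_cliques = list(list(taxa = 1:2,
                                effects = c(secure = 0, insecure = 0))),
    seed = 4))
  tr <- coh$truth
  pair <- tr$cliques[[1]]
  exact <- recovery_report(tr, list(pair))
  expect_equal(exact$jaccard, 1)
  expect_true(exact$exact)
  partial <- recovery_report(tr, list(c(pair[1], "ASV0009")))
  expect_equal(partial$jaccard, 1 / 3)
  expect_false(partial$exact)
  none <- recovery_report(tr, list())
  expect_equal(none$jaccard, 0)
})
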