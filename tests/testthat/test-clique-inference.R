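test_that("the clique indicator counts present members", {
  v <- rbind(S1 = c(A = 0.1, B = 0, C = 0.2),
             S2 = c(A = 0.3, B = 0.1, C = 0),
             S3 = c(A = 0, B = 0, C = 0.5))
  ft <- feature_table(v)
  ind <- build_indicator(ft, c("A", "B"))
  expect_identical(ind$values, c(1L, 2L, 0L))
  expect_identical(ind$harboring, c(TRUE, TRUE, FALSE))
  expect_error(build_indicator(ft, c("A", "Z")), "Z")
  expect_error(build_indicator(ft, character(0)), "empty")
})

test_that("indicator is bounded by clique size and sums member presences", {
  coh <- small_cohort(seed = 14)
  clique <- coh$truth$cliques[[2]]
  ind <- build_indicator(coh$table, clique)
  expect_true(all(ind$values >= 0 & ind$values <= length(clique)))
  by_hand <- rowSums(sapply(clique, function(tx) coh$table$values[, tx] > 0))
  expect_equal(ind$values, as.integer(by_hand))
})

test_that("exhaustive permutation p equals enumeration over all orderings", {
  # perfect monotone triple: both orderings achieve |t| = Inf -> p = 3/7
  res <- permutation_regression(c(1, 2, 3), c(1, 2, 3), exhaustive = TRUE)
  expect_equal(res$p_robust, 3 / 7)

  # independent brute-force oracle at n = 5: lm() on every permutation
  withr::with_seed(15, {
    y <- rnorm(5)
    x <- c(0, 1, 2, 0, 1)
    z <- rnorm(5)
  })
  res5 <- permutation_regression(y, x, cbind(z = z), exhaustive = TRUE)
  perms <- do.call(rbind, enum_perms(5))
  tstat <- function(yy) {
    fit <- summary(lm(yy ~ x + z))
    abs(coef(fit)[2, "t value"])
  }
  t_obs <- tstat(y)
  t_all <- apply(perms, 1, function(p) tstat(y[p]))
  expect_equal(res5$p_robust, (1 + sum(t_all >= t_obs - 1e-12)) / (1 + 120))
  expect_gte(res5$p_robust, 1 / 121)
})

test_that("permutation regression is deterministic and validates inputs", {
  withr::with_seed(16, {
    y <- rnorm(40)
    x <- rbinom(40, 2, 0.4)
    z <- matrix(rnorm(80), 40, 2)
  })
  a <- permutation_regression(y, x, z, n_permutations = 500, seed = 5)
  b <- permutation_regression(y, x, z, n_permutations = 500, seed = 5)
  expect_identical(a, b)
  expect_gte(a$p_robust, 1 / 501)
  expect_lte(a$p_robust, 1)
  expect_equal(a$ci95, c(a$beta - 1.96 * a$se, a$beta + 1.96 * a$se))
  expect_error(permutation_regression(y, rep(1, 40), z), "constant")
  expect_error(permutation_regression(y, x, z, n_permutations = 50),
               "n_permutations")
})

test_that("stratified effects recover per-stratum coefficients and prevalences", {
  coh <- generate_cohort(cohort_config(n_samples = 500, seed = 17))
  meta <- coh$metadata
  meta[, 5:12] <- pmm_impute(meta[, 5:12], seed = 2)
  eff <- stratified_effects(coh$table, meta, coh$truth$cliques[[1]],
                            n_permutations = 200, seed = 6)
  expect_equal(eff$table$stratum, c("secure", "insecure"))
  expect_equal(eff$table$n, as.vector(table(meta$food_insecure)))
  ind <- build_indicator(coh$table, coh$truth$cliques[[1]])
  for (i in 1:2) {
    sel <- meta$food_insecure == (i - 1)
    expect_equal(eff$table$n_harboring[i], sum(ind$harboring[sel]))
    expect_equal(eff$table$prevalence[i], mean(ind$harboring[sel]))
  }
  true_betas <- coh$truth$effects[[1]][c("secure", "insecure")]
  for (i in 1:2)
    expect_lt(abs(eff$table$beta[i] - true_betas[i]),
              3 * (eff$table$ci_high[i] - eff$table$beta[i]) / 1.96)
})

test_that("a stratum without the clique is flagged, not fatal", {
  coh <- small_cohort(seed = 18, n = 150)
  meta <- coh$metadata
  meta[, 5:12] <- pmm_impute(meta[, 5:12], seed = 3)
  tbl <- coh$table
  # erase the clique from the insecure stratum
  tbl$values[meta$food_insecure == 1, coh$truth$cliques[[1]]] <- 0
  expect_warning(
    eff <- stratified_effects(tbl, meta, coh$truth$cliques[[1]],
                              n_permutations = 200, seed = 7),
    "constant")
  expect_true(is.na(eff$table$beta[eff$table$stratum == "insecure"]))
  expect_false(is.na(eff$table$beta[eff$table$stratum == "secure"]))
})

test_that("cross-stratum validation runs on the opposite stratum", {
  coh <- small_cohort(seed = 19, n = 200)
  meta <- coh$metadata
  meta[, 5:12] <- pmm_impute(meta[, 5:12], seed = 4)
  res <- cross_stratum_validate(coh$table, meta, coh$truth$cliques[[1]],
                                discovered_in = "insecure",
                                n_permutations = 200, seed = 8)
  expect_equal(attr(res, "stratum"), "secure")
  expect_equal(res$n, sum(meta$food_insecure == 0))
  expect_error(
    cross_stratum_validate(coh$table, meta, character(0),
                           discovered_in = "secure"),
    "empty")
})
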