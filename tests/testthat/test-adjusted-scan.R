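test_that("a perfect line is fit exactly", {
  fit <- fit_adjusted_lm(c(1, 2, 3), c(0, 1, 2))
  expect_equal(fit$beta, 1)
  expect_equal(fit$p_raw < 1e-10, TRUE)
})

test_that("OLS matches the normal-equations solution", {
  withr::with_seed(11, {
    for (i in seq_len(100)) {
      n <- 50
      Z <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
      x <- rnorm(n)
      y <- rnorm(n)
      fit <- fit_adjusted_lm(y, x, Z)
      X <- cbind(1, x, Z)
      XtXinv <- solve(crossprod(X))
      beta <- XtXinv %*% crossprod(X, y)
      expect_equal(fit$beta, beta[2], tolerance = 1e-8)
      sigma2 <- sum((y - X %*% beta)^2) / (n - ncol(X))
      expect_equal(fit$se, sqrt(sigma2 * XtXinv[2, 2]), tolerance = 1e-8)
      expect_equal(fit$ci_low, fit$beta - 1.96 * fit$se)
    }
  })
})

test_that("rank-deficient designs fail naming the collinear column", {
  n <- 30
  withr::with_seed(2, {
    x <- rnorm(n)
    Z <- cbind(dup = 2 * x, ok = rnorm(n))
    expect_error(fit_adjusted_lm(rnorm(n), x, Z), "dup")
  })
})

test_that("a null exposure estimates zero within Monte Carlo error", {
  withr::with_seed(3, {
    x <- rnorm(2000)
    y <- rnorm(2000)
    fit <- fit_adjusted_lm(y, x)
    expect_lt(abs(fit$beta), 3 * fit$se)
  })
})

test_that("the per-taxon scan applies Benjamini-Hochberg within the stratum", {
  coh <- small_cohort(seed = 9, n = 150)
  meta <- coh$metadata
  meta[, 5:12] <- pmm_impute(meta[, 5:12], seed = 1)
  fits <- asv_scan(coh$table, meta, "all")
  expect_equal(nrow(fits), ncol(coh$table$values))
  # brute-force BH: sort, p * m / rank, cumulative min from the tail
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  expect_equal(fits$p_fdr, brute_bh(fits$p_raw), tolerance = 1e-12)
  expect_error(asv_scan(coh$table, meta[1:8, ], "all"), "at least")
})

test_that("BH agrees with brute force on worked and random p-vectors", {
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  expect_equal(p.adjust(c(0.005, 0.01, 0.03, 0.04), "BH"),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(p.adjust(1, "BH"), 1)
  expect_equal(p.adjust(rep(1, 5), "BH"), rep(1, 5))
  withr::with_seed(8, {
    for (i in 1:20) {
      p <- runif(sample(1:40, 1))
      expect_equal(p.adjust(p, "BH"), brute_bh(p))
    }
  })
})

test_that("volcano table transforms p-values onto the -log10 scale", {
  fits <- data.frame(taxon_id = c("t1", "t2", "t3"), beta = c(1, -1, 0),
                     p_raw = c(0.05, 1, 0.01))
  v <- volcano_data(fits)
  expect_equal(v$neg_log10_p, c(1.3010, 0, 2), tolerance = 1e-4)
  expect_equal(attr(v, "reference_p"), c(0.05, 0.01))
  expect_error(volcano_data(fits[0, ]), "empty")
})

test_that("descriptive table reproduces printed exact-test p-values", {
  smoker <- meta_from_2x2(rbind(secure = c(126, 166), insecure = c(44, 24)),
                          "ever_smoker")
  d <- descriptive_table(smoker, continuous = character(0),
                         categorical = "ever_smoker")
  expect_lt(abs(d$p - 0.002), 0.0005)
  expect_equal(d$test, "exact")

  abx <- meta_from_2x2(rbind(secure = c(97, 195), insecure = c(27, 41)),
                       "antibiotics_year")
  d2 <- descriptive_table(abx, continuous = character(0),
                          categorical = "antibiotics_year")
  expect_lt(abs(d2$p - 0.32), 0.01)

  balanced <- meta_from_2x2(rbind(secure = c(50, 50), insecure = c(50, 50)),
                            "ever_smoker")
  d3 <- descriptive_table(balanced, continuous = character(0),
                          categorical = "ever_smoker")
  expect_equal(d3$p, 1)
})

test_that("descriptive table uses rank-sum for continuous variables", {
  coh <- small_cohort(seed = 10, n = 200)
  d <- descriptive_table(coh$metadata)
  expect_true(all(d$test[d$type == "continuous"] == "rank-sum"))
  expect_true(all(d$p >= 0 & d$p <= 1))
  expect_match(d$overall[d$variable == "age"], "^[0-9.]+ \\([0-9.]+\\)$")
})
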