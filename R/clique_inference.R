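# Stage 2 of MiCA: clique-indicator construction, covariate-adjusted
# regression with permutation p-values, stratified effect-modification
# contrasts, and cross-stratum validation.

#' Build a per-sample clique indicator
#'
#' The indicator counts, for each sample, how many of the clique's taxa are
#' present (relative abundance strictly greater than zero). For a clique of k
#' taxa the indicator ranges over 0..k; a sample "harbors" the clique when
#' the indicator is at least 1.
#'
#' @param table A [feature_table()].
#' @param clique Character vector of taxon ids, or a clique object with a
#'   `$taxa` element.
#' @return A `clique_indicator`: list with `clique` (the taxa), `values`
#'   (integer per sample), and `harboring` (logical, `values >= 1`).
#' @export
build_indicator <- function(table, clique) {
  stopifnot(inherits(table, "feature_table"))
  if (is.list(clique)) clique <- clique$taxa
  clique <- as.character(clique)
  if (length(clique) == 0L) stopf("`clique` is empty")
  missing <- setdiff(clique, colnames(table$values))
  if (length(missing) > 0L)
    stopf("unknown taxon/taxa in clique: %s", paste(missing, collapse = ", "))
  values <- as.integer(rowSums(table$values[, clique, drop = FALSE] > 0))
  structure(list(clique = clique, values = values,
                 harboring = values >= 1L),
            class = "clique_indicator")
}

# |t|-statistics of the second design column for every outcome column of Y,
# computed in one linear-algebra pass (used for the permutation null).
t_stats <- function(X, Y, XtXinv, df) {
  H <- XtXinv %*% t(X)              # p x n
  beta <- H %*% Y                   # p x B
  rss <- colSums((Y - X %*% beta)^2)
  # Residuals that are pure floating-point dust mean a saturated fit.
  rss[rss <= colSums(Y^2) * 1e-20] <- 0
  sigma2 <- rss / df
  se <- sqrt(sigma2 * XtXinv[2L, 2L])
  tt <- beta[2L, ] / se
  tt[se == 0] <- sign(beta[2L, se == 0]) * Inf
  tt
}

#' Covariate-adjusted regression with a permutation p-value
#'
#' Fits `outcome ~ indicator + covariates` by OLS and computes a permutation
#' p-value by permuting the outcome vector wholesale and recomputing the
#' |t|-statistic of the exposure coefficient:
#' `p = (1 + #permutations with |t| >= |t_obs|) / (1 + n_permutations)`
#' (add-one smoothing, so p is never zero and never below
#' `1 / (n_permutations + 1)`).
#'
#' @param outcome Numeric outcome vector.
#' @param indicator A [build_indicator()] result or numeric exposure vector;
#'   must not be constant.
#' @param covariates Optional complete covariate matrix/data.frame.
#' @param n_permutations Number of random permutations (>= 100; default
#'   1e5).
#' @param seed Integer seed; results are deterministic given it.
#' @param exhaustive If `TRUE`, enumerate all `n!` permutations instead of
#'   sampling (requires `n <= 8`); `n_permutations` is ignored.
#' @return A `permutation_result`: list with `beta`, `se`, `ci95`, `t_obs`,
#'   `p_robust`, `n_permutations`, `n`, `seed`.
#' @export
permutation_regression <- function(outcome, indicator, covariates = NULL,
                                   n_permutations = 1e5, seed = 1L,
                                   exhaustive = FALSE) {
  if (inherits(indicator, "clique_indicator")) indicator <- indicator$values
  indicator <- as.numeric(indicator)
  if (length(unique(indicator)) < 2L)
    stopf("constant indicator: no exposure variation to test")
  if (anyNA(outcome)) stopf("`outcome` must be complete")
  n <- length(outcome)
  X <- build_design(indicator, covariates, "indicator")
  fit <- ols_fit(outcome, X)
  beta <- fit$beta[2L]
  se <- fit$se[2L]
  t_obs <- abs(t_stats(X, matrix(outcome, ncol = 1L), fit$XtXinv, fit$df))

  if (exhaustive) {
    if (n > 8L) stopf("exhaustive enumeration supported only for n <= 8")
    perms <- all_permutations(n)
  } else {
    n_permutations <- check_count(n_permutations, "n_permutations", min = 100L)
    perms <- NULL
  }

  count <- 0L
  total <- 0L
  # The observed statistic and the permuted ones travel through differently
  # batched linear algebra; a relative tolerance keeps exact ties counted.
  thresh <- if (is.finite(t_obs)) t_obs - 1e-8 * (1 + abs(t_obs)) else t_obs
  with_seed(seed, {
    chunk <- 10000L
    if (!is.null(perms)) {
      idx_blocks <- split(seq_len(nrow(perms)),
                          ceiling(seq_len(nrow(perms)) / chunk))
      for (blk in idx_blocks) {
        Y <- matrix(outcome[t(perms[blk, , drop = FALSE])], nrow = n)
        tp <- abs(t_stats(X, Y, fit$XtXinv, fit$df))
        count <- count + sum(tp >= thresh)
        total <- total + length(tp)
      }
    } else {
      remaining <- as.integer(n_permutations)
      while (remaining > 0L) {
        b <- min(chunk, remaining)
        Y <- vapply(seq_len(b), function(i) outcome[sample.int(n)],
                    numeric(n))
        tp <- abs(t_stats(X, Y, fit$XtXinv, fit$df))
        count <- count + sum(tp >= thresh)
        total <- total + b
        remaining <- remaining - b
      }
    }
  })

  structure(list(beta = beta, se = se,
                 ci95 = c(beta - 1.96 * se, beta + 1.96 * se),
                 t_obs = unname(t_obs),
                 p_robust = (1 + count) / (1 + total),
                 n_permutations = total, n = n, seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("beta = %.4f (95%% CI %.4f, %.4f), robust p = %.4g [%d permutations, n = %d]\n",
              x$beta, x$ci95[1], x$ci95[2], x$p_robust, x$n_permutations,
              x$n))
  invisible(x)
}

#' Stratified clique-indicator effects (effect modification)
#'
#' Builds the clique indicator, splits the cohort by food-insecurity status,
#' and fits the covariate-adjusted permutation regression within each
#' stratum, reporting per-stratum coefficients, permutation p-values, and
#' harboring prevalences, as a forest-plot-ready table. A stratum in which
#' the indicator has no variation (e.g. the clique is absent from every
#' sample) is flagged with an `NA` fit and a warning rather than an error, so
#' the other stratum still reports.
#'
#' @param table A [feature_table()].
#' @param meta Metadata with `rci`, `food_insecure`, and covariates
#'   (complete).
#' @param clique Taxon ids (or clique object).
#' @param covariates Covariate column names; default standard set.
#' @param n_permutations,seed Passed to [permutation_regression()].
#' @return A `stratified_effects` object: list with `fits` (named list of
#'   `permutation_result` or `NULL`), and `table`, a data.frame with one row
#'   per stratum: `stratum`, `beta`, `ci_low`, `ci_high`, `p_robust`, `n`,
#'   `n_harboring`, `prevalence`.
#' @export
stratified_effects <- function(table, meta, clique,
                               covariates = default_covariates,
                               n_permutations = 1e5, seed = 1L) {
  ind <- build_indicator(table, clique)
  strata <- c(secure = 0, insecure = 1)
  seeds <- child_seeds(seed, length(strata))
  fits <- list()
  rows <- list()
  for (i in seq_along(strata)) {
    nm <- names(strata)[i]
    sel <- meta$food_insecure == strata[[i]]
    if (!any(sel)) stopf("stratum '%s' is empty", nm)
    Z <- as.matrix(meta[sel, covariates, drop = FALSE])
    if (sum(sel) < length(covariates) + 2L)
      stopf("stratum '%s' has %d samples; need at least %d", nm, sum(sel),
            length(covariates) + 2L)
    vals <- ind$values[sel]
    fit <- if (length(unique(vals)) < 2L) {
      warnf("clique indicator is constant in stratum '%s'; fit skipped", nm)
      NULL
    } else {
      permutation_regression(meta$rci[sel], vals, Z,
                             n_permutations = n_permutations,
                             seed = seeds[i])
    }
    fits[[nm]] <- fit
    rows[[nm]] <- data.frame(
      stratum = nm,
      beta = if (is.null(fit)) NA_real_ else fit$beta,
      ci_low = if (is.null(fit)) NA_real_ else fit$ci95[1],
      ci_high = if (is.null(fit)) NA_real_ else fit$ci95[2],
      p_robust = if (is.null(fit)) NA_real_ else fit$p_robust,
      n = sum(sel), n_harboring = sum(ind$harboring[sel]),
      prevalence = mean(ind$harboring[sel]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(clique = ind$clique, fits = fits, table = out),
            class = "stratified_effects")
}

#' @export
print.stratified_effects <- function(x, ...) {
  cat(sprintf("Clique {%s}\n", paste(x$clique, collapse = ", ")))
  print(x$table, digits = 4)
  invisible(x)
}

#' Validate a clique in the opposite stratum
#'
#' A clique discovered in one food-security stratum is re-tested with the
#' same adjusted permutation regression on the out-of-bag samples of the
#' other stratum.
#'
#' @inheritParams stratified_effects
#' @param discovered_in `"secure"` or `"insecure"`: the stratum the clique
#'   was discovered in; the regression runs on the other one.
#' @return A `permutation_result` with attribute `stratum` naming the
#'   validation stratum.
#' @export
cross_stratum_validate <- function(table, meta, clique,
                                   discovered_in = c("insecure", "secure"),
                                   covariates = default_covariates,
                                   n_permutations = 1e5, seed = 1L) {
  discovered_in <- match.arg(discovered_in)
  other <- if (discovered_in == "insecure") "secure" else "insecure"
  sel <- meta$food_insecure == (other == "insecure")
  ind <- build_indicator(table, clique)
  Z <- as.matrix(meta[sel, covariates, drop = FALSE])
  res <- permutation_regression(meta$rci[sel], ind$values[sel], Z,
                                n_permutations = n_permutations, seed = seed)
  attr(res, "stratum") <- other
  res
}
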