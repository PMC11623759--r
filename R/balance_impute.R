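# Sensitivity machinery: predictive-mean-matching imputation for sparse
# covariate missingness and subclassification covariate-balance diagnostics.

#' Predictive-mean-matching imputation
#'
#' For each column with missing cells, a linear model of that column on all
#' other covariates is fit on the complete rows; every missing cell is filled
#' with the *observed* value of a donor drawn uniformly from the `k_donors`
#' complete cases whose model predictions are closest to the target row's
#' prediction. Imputed values therefore always come from the observed support
#' of the column. Rows used only as predictors have their own missing cells
#' mean-filled for the prediction step.
#'
#' @param covariates Numeric data.frame or matrix (binary covariates coded
#'   0/1) with missing cells; per-column missingness must be below 50% and
#'   each column needs at least `k_donors` observed rows.
#' @param k_donors Donor-pool size (default 5).
#' @param seed Integer seed; deterministic given it.
#' @return A completed object of the same class and dimensions.
#' @export
pmm_impute <- function(covariates, k_donors = 5L, seed = 1L) {
  k_donors <- check_count(k_donors, "k_donors")
  was_df <- is.data.frame(covariates)
  M <- as.matrix(covariates)
  if (!is.numeric(M)) stopf("covariates must be numeric (code binaries 0/1)")
  if (!anyNA(M)) return(covariates)
  if (is.null(colnames(M))) colnames(M) <- paste0("V", seq_len(ncol(M)))
  miss_frac <- colMeans(is.na(M))
  if (any(miss_frac == 1))
    stopf("column(s) entirely missing: %s",
          paste(colnames(M)[miss_frac == 1], collapse = ", "))
  if (any(miss_frac >= 0.5))
    stopf("column(s) with >= 50%% missingness: %s",
          paste(colnames(M)[miss_frac >= 0.5], collapse = ", "))
  # Mean-filled copy used only to form predictions.
  fill <- M
  for (j in seq_len(ncol(fill)))
    fill[is.na(fill[, j]), j] <- mean(M[, j], na.rm = TRUE)
  out <- M
  with_seed(seed, {
    for (j in which(miss_frac > 0)) {
      obs <- which(!is.na(M[, j]))
      mis <- which(is.na(M[, j]))
      if (length(obs) < k_donors)
        stopf("column '%s' has fewer than k_donors observed rows",
              colnames(M)[j])
      Xj <- cbind(1, fill[, -j, drop = FALSE])
      bj <- qr.coef(qr(Xj[obs, , drop = FALSE]), M[obs, j])
      bj[is.na(bj)] <- 0  # collinear predictors contribute nothing
      pred <- as.vector(Xj %*% bj)
      for (i in mis) {
        d <- abs(pred[obs] - pred[i])
        donors <- obs[order(d, obs)[seq_len(k_donors)]]
        out[i, j] <- M[donors[sample.int(length(donors), 1L)], j]
      }
    }
  })
  if (was_df) {
    res <- as.data.frame(out)
    names(res) <- names(covariates)
    res
  } else out
}

#' Covariate balance by propensity-score subclassification
#'
#' Scores each sample with a linear model of the binary exposure on the
#' covariates, cuts the sample into `n_subclasses` score quantile classes,
#' and reports each covariate's standardized mean difference (SMD; mean
#' difference between exposure groups over the pooled SD) before
#' subclassification and as the subclass-size-weighted average afterwards.
#' A subclass containing only one exposure group is merged with its
#' neighbour, with a warning.
#'
#' @param exposure Binary vector (1 = exposed, e.g. harboring the clique).
#' @param covariates Complete numeric matrix/data.frame.
#' @param n_subclasses Number of propensity subclasses (default 5).
#' @return A `balance_report`: list with `table` (data.frame `covariate`,
#'   `smd_before`, `smd_after`, sorted by decreasing `|smd_before|`),
#'   `n_subclasses` (after any merging), and `subclass` (assignments).
#' @export
subclass_balance <- function(exposure, covariates, n_subclasses = 5L) {
  n_subclasses <- check_count(n_subclasses, "n_subclasses")
  exposure <- as.integer(exposure)
  if (!is_binary(exposure) || anyNA(exposure))
    stopf("`exposure` must be complete and binary")
  if (length(unique(exposure)) < 2L)
    stopf("both exposure groups must be non-empty")
  Z <- as.matrix(covariates)
  if (anyNA(Z)) stopf("covariates must be complete; impute first")
  if (is.null(colnames(Z))) colnames(Z) <- paste0("V", seq_len(ncol(Z)))
  score <- fitted(lm(exposure ~ Z))
  breaks <- unique(quantile(score, seq(0, 1, length.out = n_subclasses + 1L),
                            type = 7, names = FALSE))
  sub <- as.integer(cut(score, breaks, include.lowest = TRUE))
  # Merge one-group subclasses into their lower neighbour.
  repeat {
    bad <- NULL
    for (s in sort(unique(sub)))
      if (length(unique(exposure[sub == s])) < 2L) { bad <- s; break }
    if (is.null(bad)) break
    if (length(unique(sub)) == 1L)
      stopf("subclassification failed: a single class lacks both groups")
    neighbours <- sort(unique(sub))
    pos <- match(bad, neighbours)
    target <- if (pos > 1L) neighbours[pos - 1L] else neighbours[pos + 1L]
    warnf("subclass %d contains a single exposure group; merged with %d",
          bad, target)
    sub[sub == bad] <- target
  }
  sub <- as.integer(factor(sub))

  tab <- do.call(rbind, lapply(colnames(Z), function(v) {
    x <- Z[, v]
    pooled_sd <- sqrt((var(x[exposure == 1L]) + var(x[exposure == 0L])) / 2)
    if (!is.finite(pooled_sd) || pooled_sd == 0) pooled_sd <- 1
    before <- (mean(x[exposure == 1L]) - mean(x[exposure == 0L])) / pooled_sd
    wsum <- 0
    acc <- 0
    for (s in unique(sub)) {
      xs <- x[sub == s]
      es <- exposure[sub == s]
      acc <- acc + length(xs) * (mean(xs[es == 1L]) - mean(xs[es == 0L])) /
        pooled_sd
      wsum <- wsum + length(xs)
    }
    data.frame(covariate = v, smd_before = before, smd_after = acc / wsum)
  }))
  tab <- tab[order(-abs(tab$smd_before)), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, n_subclasses = length(unique(sub)),
                 subclass = sub),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report> %d subclasses\n", x$n_subclasses))
  print(x$table, digits = 3)
  invisible(x)
}
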