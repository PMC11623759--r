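# Covariate-adjusted linear models: the pooled exposure model, per-taxon
# quartile scans with FDR, volcano tables, and descriptive statistics.

# The default adjustment set used throughout the analysis.
default_covariates <- c("age", "race_white_nh", "bmi", "gender_female",
                        "pet_owner", "ever_smoker", "fiber_g",
                        "antibiotics_year")

# Ordinary least squares via QR with explicit collinearity detection.
# Returns coefficients, standard errors, df, and the unscaled covariance.
ols_fit <- function(y, X) {
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stopf("need n > number of model columns (%d <= %d)", n, p)
  qrx <- qr(X)
  if (qrx$rank < p) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):p]]
    stopf("rank-deficient design; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  res <- y - X %*% beta
  df <- n - p
  sigma2 <- sum(res^2) / df
  R <- qr.R(qrx)
  V <- chol2inv(R)
  piv <- qrx$pivot
  XtXinv <- matrix(NA_real_, p, p)
  XtXinv[piv, piv] <- V
  list(beta = as.vector(beta), se = sqrt(sigma2 * diag(XtXinv)),
       df = df, sigma2 = sigma2, XtXinv = XtXinv, qr = qrx)
}

# Assemble the design matrix: intercept, exposure, covariates.
build_design <- function(exposure, covariates, exposure_name = "exposure") {
  X <- cbind(1, as.numeric(exposure))
  colnames(X) <- c("(Intercept)", exposure_name)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.numeric(covariates)) stopf("covariates must be numeric")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  if (anyNA(X)) stopf("design matrix contains missing values; impute first")
  X
}

#' Covariate-adjusted linear model for a single exposure
#'
#' Fits `outcome ~ exposure + covariates` by ordinary least squares and
#' returns the exposure coefficient with a normal-theory 95% CI
#' (`beta +/- 1.96 se`) and a two-sided t-test p-value.
#'
#' @param outcome Numeric outcome vector (e.g. the RCI score).
#' @param exposure Numeric exposure vector.
#' @param covariates Optional numeric matrix/data.frame of adjustment
#'   covariates (no missing values; see [pmm_impute()]).
#' @param exposure_name Label for the exposure.
#' @param stratum Label recorded with the fit (e.g. `"insecure"`).
#' @return An `adjusted_fit`: a one-row data.frame with `exposure`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `p_raw`, `n`, `stratum`.
#' @export
fit_adjusted_lm <- function(outcome, exposure, covariates = NULL,
                            exposure_name = "exposure", stratum = "all") {
  if (anyNA(outcome) || anyNA(exposure))
    stopf("outcome and exposure must be complete")
  X <- build_design(exposure, covariates, exposure_name)
  fit <- ols_fit(outcome, X)
  beta <- fit$beta[2L]
  se <- fit$se[2L]
  tval <- beta / se
  out <- data.frame(exposure = exposure_name, beta = beta, se = se,
                    ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
                    p_raw = 2 * pt(-abs(tval), fit$df), n = nrow(X),
                    stratum = stratum, row.names = NULL)
  class(out) <- c("adjusted_fit", "data.frame")
  out
}

#' Per-taxon adjusted association scan with FDR correction
#'
#' Quartile-encodes each taxon's relative abundance (see [quartile_encode()];
#' encoding is computed on the analysis set actually modelled) and fits one
#' covariate-adjusted linear model per taxon. Raw p-values are corrected for
#' the false discovery rate with Benjamini-Hochberg across all taxa in the
#' scan.
#'
#' @param table A prevalence-filtered [feature_table()] of relative
#'   abundances.
#' @param meta Metadata data.frame containing `rci`, `food_insecure`, and the
#'   adjustment covariates (complete).
#' @param stratum `"all"`, `"secure"`, or `"insecure"`; rows are restricted
#'   accordingly.
#' @param covariates Covariate column names; defaults to the standard
#'   adjustment set.
#' @return A data.frame of fits (one row per taxon) with `taxon_id`, `label`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `p_raw`, `p_fdr`, `n`, `stratum`.
#' @export
asv_scan <- function(table, meta, stratum = c("all", "secure", "insecure"),
                     covariates = default_covariates) {
  stopifnot(inherits(table, "feature_table"))
  stratum <- match.arg(stratum)
  idx <- switch(stratum, all = rep(TRUE, nrow(meta)),
                secure = meta$food_insecure == 0,
                insecure = meta$food_insecure == 1)
  meta <- meta[idx, , drop = FALSE]
  vals <- table$values[idx, , drop = FALSE]
  Z <- as.matrix(meta[, covariates, drop = FALSE])
  if (nrow(meta) < length(covariates) + 2L)
    stopf("stratum '%s' has %d samples; need at least %d", stratum,
          nrow(meta), length(covariates) + 2L)
  fits <- lapply(colnames(vals), function(tx) {
    q <- suppressWarnings(quartile_encode(vals[, tx]))
    fit <- fit_adjusted_lm(meta$rci, q, Z, exposure_name = tx,
                           stratum = stratum)
    fit
  })
  out <- do.call(rbind, fits)
  names(out)[names(out) == "exposure"] <- "taxon_id"
  out$label <- if (is.null(table$taxon_labels)) out$taxon_id else
    unname(table$taxon_labels[out$taxon_id])
  out$p_fdr <- p.adjust(out$p_raw, method = "BH")
  out[, c("taxon_id", "label", "beta", "se", "ci_low", "ci_high",
          "p_raw", "p_fdr", "n", "stratum")]
}

#' Volcano-plot table
#'
#' Turns a set of per-taxon fits into a volcano table of effect size against
#' `-log10(p_raw)`, with reference lines at p = 0.05 and p = 0.01 recorded as
#' attributes (drawn by [plot_volcano()]).
#'
#' @param fits Output of [asv_scan()] (or any data.frame with `beta`,
#'   `p_raw`, and a `label`/`taxon_id` column).
#' @return A data.frame with `taxon_id`, `label`, `beta`, `p_raw`,
#'   `neg_log10_p`; attribute `reference_p` holds `c(0.05, 0.01)`.
#' @export
volcano_data <- function(fits) {
  if (NROW(fits) == 0L) stopf("`fits` is empty")
  label <- if (!is.null(fits$label)) fits$label else fits$taxon_id
  out <- data.frame(taxon_id = fits$taxon_id, label = label,
                    beta = fits$beta, p_raw = fits$p_raw,
                    neg_log10_p = -log10(fits$p_raw))
  attr(out, "reference_p") <- c(0.05, 0.01)
  out
}

#' Descriptive (Table-1 style) cohort summary by stratum
#'
#' Continuous variables are summarised as mean (SD) and compared across
#' strata with a two-sided Wilcoxon rank-sum test (normal approximation with
#' tie correction); categorical variables as n (%) with Fisher's exact test
#' (two-sided by summing table probabilities no larger than the observed
#' one).
#'
#' @param meta Metadata data.frame with a complete `food_insecure` column.
#' @param continuous,categorical Column names to summarise; defaults cover
#'   the standard cohort sheet (plus `shannon` if present).
#' @return A data.frame with one row per variable: `variable`, `type`,
#'   `overall`, `secure`, `insecure`, `test`, `p`.
#' @export
descriptive_table <- function(meta,
                              continuous = intersect(
                                c("age", "bmi", "fiber_g", "minicog",
                                  "shannon"), names(meta)),
                              categorical = intersect(
                                c("race_white_nh", "gender_female",
                                  "pet_owner", "ever_smoker",
                                  "antibiotics_year"), names(meta))) {
  if (anyNA(meta$food_insecure)) stopf("`food_insecure` must be complete")
  grp <- factor(meta$food_insecure, levels = c(0, 1),
                labels = c("secure", "insecure"))
  msd <- function(x) sprintf("%.2f (%.2f)", mean(x, na.rm = TRUE),
                             sd(x, na.rm = TRUE))
  npct <- function(x) sprintf("%d (%.2f%%)", sum(x == 1, na.rm = TRUE),
                              100 * mean(x == 1, na.rm = TRUE))
  rows <- list()
  for (v in continuous) {
    x <- meta[[v]]
    p <- suppressWarnings(
      wilcox.test(x ~ grp, exact = FALSE, correct = TRUE)$p.value)
    rows[[v]] <- data.frame(variable = v, type = "continuous",
                            overall = msd(x), secure = msd(x[grp == "secure"]),
                            insecure = msd(x[grp == "insecure"]),
                            test = "rank-sum", p = p)
  }
  for (v in categorical) {
    x <- meta[[v]]
    tab <- table(grp, factor(x, levels = sort(unique(x[!is.na(x)]))))
    p <- fisher.test(tab)$p.value
    rows[[v]] <- data.frame(variable = v, type = "categorical",
                            overall = npct(x), secure = npct(x[grp == "secure"]),
                            insecure = npct(x[grp == "insecure"]),
                            test = "exact", p = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
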