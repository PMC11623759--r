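#' Derive food-insecurity status from three screening questions
#'
#' The exposure strata come from three yes/no survey questions (use of
#' emergency food services, concern about having enough food, authorization
#' for food-stamp benefits, each over the last 12 months). A participant is
#' classified food-insecure if they answered yes to any of the three.
#'
#' @param q1,q2,q3 Vectors of responses; `TRUE`/`FALSE`, 0/1, or
#'   `"yes"`/`"no"` (case-insensitive) are accepted.
#' @return Integer vector, 1 = food-insecure, 0 = food-secure.
#' @export
derive_food_insecurity <- function(q1, q2, q3) {
  as_yes <- function(q) {
    if (is.character(q) || is.factor(q)) {
      q <- tolower(as.character(q))
      bad <- !q %in% c("yes", "no", NA)
      if (any(bad)) stopf("unrecognised response(s): %s",
                          paste(unique(q[bad]), collapse = ", "))
      q == "yes"
    } else {
      if (!all(q %in% c(0, 1, NA))) stopf("responses must be yes/no or 0/1")
      as.logical(q)
    }
  }
  as.integer(as_yes(q1) | as_yes(q2) | as_yes(q3))
}

#' Transform a mini-cog word-recall score into the RCI outcome
#'
#' The mini-cog recall count (0-3 words, higher = better recall) is inverted
#' and log-transformed so that the modelled outcome increases with risk of
#' cognitive impairment (RCI) and its right skew is tamed:
#' `rci = log(1 + (3 - minicog))`. The +1 offset is needed because a perfect
#' recall inverts to 0. `invert_outcome()` is the exact inverse, mapping an
#' RCI value back to the integer score.
#'
#' @param minicog Integer vector of scores in `{0, 1, 2, 3}`.
#' @return Numeric vector of RCI values; strictly decreasing in `minicog`,
#'   with `transform_outcome(3) == 0`.
#' @export
transform_outcome <- function(minicog) {
  if (any(is.na(minicog)) || !all(minicog %in% 0:3))
    stopf("`minicog` must be integers in 0..3")
  log(1 + (3 - minicog))
}

#' @rdname transform_outcome
#' @param rci RCI values as produced by `transform_outcome()`.
#' @export
invert_outcome <- function(rci) {
  score <- as.integer(round(3 - (exp(rci) - 1)))
  if (any(is.na(score)) || !all(score %in% 0:3))
    stopf("`rci` is not in the image of `transform_outcome()`")
  score
}

#' Convert a count matrix to per-sample relative abundances
#'
#' @param counts Non-negative matrix (samples x taxa) or [feature_table()].
#' @return A [feature_table()] whose rows each sum to 1.
#' @export
to_relative_abundance <- function(counts) {
  labels <- NULL
  if (inherits(counts, "feature_table")) {
    labels <- counts$taxon_labels
    counts <- counts$values
  }
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  tot <- rowSums(counts)
  if (any(tot <= 0)) {
    bad <- rownames(counts)[tot <= 0]
    if (is.null(bad)) bad <- which(tot <= 0)
    stopf("sample(s) with zero total abundance: %s",
          paste(head(bad, 5L), collapse = ", "))
  }
  feature_table(counts / tot, taxon_labels = labels)
}

#' Drop rare taxa by prevalence
#'
#' Retains taxa whose presence fraction (relative abundance strictly greater
#' than zero) exceeds `threshold` strictly. Remaining abundances are *not*
#' rescaled, so row sums may fall below 1 after filtering; downstream models
#' treat each taxon marginally, so renormalisation would only distort the
#' retained abundances.
#'
#' @param table A [feature_table()] of relative abundances.
#' @param threshold Prevalence fraction; a taxon is kept iff
#'   `mean(abundance > 0) > threshold`. Default 0.05.
#' @return The filtered [feature_table()]. Idempotent.
#' @export
prevalence_filter <- function(table, threshold = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  check_probability(threshold, "threshold")
  keep <- colMeans(table$values > 0) > threshold
  ft_subset(table, taxa = keep)
}

#' Shannon alpha diversity
#'
#' Computes `H = -sum(p_i log p_i)` (natural log) over the non-zero entries of
#' each sample's composition, after renormalising to proportions. The
#' computation is delegated to [vegan::diversity()].
#'
#' @param x Non-negative vector (one sample), matrix, or [feature_table()].
#' @return A scalar for vector input, otherwise a named vector per sample.
#' @export
shannon_diversity <- function(x) {
  if (inherits(x, "feature_table")) x <- x$values
  if (is.matrix(x)) {
    if (any(rowSums(x) <= 0)) stopf("every sample needs positive abundance")
    return(vegan::diversity(x, index = "shannon"))
  }
  if (any(x < 0)) stopf("abundances must be non-negative")
  if (sum(x) <= 0) stopf("all-zero composition has no diversity")
  vegan::diversity(x, index = "shannon")
}

#' Encode a numeric vector as quartiles 1-4
#'
#' Values are binned by the empirical quartile cut-points (type-7 sample
#' quantiles); a value equal to a cut-point falls in the lower quartile.
#' Zero-inflated taxa need a tie rule: whenever a single repeated value makes
#' up more than 25% of the vector (typically structural zeros), that entire
#' mass is coded 1 and the remaining values are quartile-coded among
#' themselves. A constant vector is coded all-1 with a warning.
#'
#' @param values Numeric vector, length >= 4.
#' @return Integer vector of codes in 1..4.
#' @export
quartile_encode <- function(values) {
  if (!is.numeric(values) || length(values) < 4L)
    stopf("`values` must be a numeric vector of length >= 4")
  if (anyNA(values)) stopf("`values` must be complete")
  quartile_codes(values, warn_constant = TRUE)
}

quartile_codes <- function(v, warn_constant = FALSE, mass_rule = TRUE) {
  if (diff(range(v)) == 0) {
    if (warn_constant) warnf("constant vector: all values coded 1")
    return(rep.int(1L, length(v)))
  }
  if (mass_rule) {
    tab <- table(v)
    if (max(tab) > 0.25 * length(v)) {
      mval <- as.numeric(names(tab)[which.max(tab)])
      out <- integer(length(v))
      out[v == mval] <- 1L
      out[v != mval] <- quartile_codes(v[v != mval], mass_rule = FALSE)
      return(out)
    }
  }
  q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  1L + (v > q[1L]) + (v > q[2L]) + (v > q[3L])
}
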