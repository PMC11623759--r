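# Plot builders (ggplot2). Each returns the ggplot object; callers save it.

#' Volcano plot of per-taxon associations
#'
#' Effect size against `-log10(p_raw)` with horizontal reference lines at
#' p = 0.05 (red) and p = 0.01 (black).
#'
#' @param fits Output of [asv_scan()] or [volcano_data()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(fits) {
  v <- if (is.null(fits$neg_log10_p)) volcano_data(fits) else fits
  ggplot2::ggplot(v, ggplot2::aes(x = .data$beta, y = .data$neg_log10_p)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(0.05), colour = "red") +
    ggplot2::geom_hline(yintercept = -log10(0.01), colour = "black") +
    ggplot2::labs(x = "Adjusted beta (per quartile)",
                  y = expression(-log[10](p)))
}

#' Forest plot of stratified clique effects
#'
#' Per-stratum adjusted beta with 95% CI and a red reference line at zero.
#'
#' @param effects A [stratified_effects()] object or its `$table`.
#' @return A ggplot object.
#' @export
plot_forest <- function(effects) {
  tab <- if (inherits(effects, "stratified_effects")) effects$table else
    effects
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$beta, y = .data$stratum)) +
    ggplot2::geom_vline(xintercept = 0, colour = "red") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.15) +
    ggplot2::labs(x = "Adjusted beta (clique indicator)", y = NULL)
}

#' Love plot of covariate balance
#'
#' Absolute standardized mean differences before and after
#' subclassification, sorted by the pre-balance SMD, with a dashed reference
#' at 0.1.
#'
#' @param report A [subclass_balance()] result.
#' @return A ggplot object.
#' @export
plot_love <- function(report) {
  tab <- report$table
  long <- data.frame(
    covariate = factor(rep(tab$covariate, 2L),
                       levels = rev(tab$covariate)),
    smd = abs(c(tab$smd_before, tab$smd_after)),
    stage = rep(c("before", "after"), each = nrow(tab)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$smd, y = .data$covariate,
                                     colour = .data$stage)) +
    ggplot2::geom_vline(xintercept = 0.1, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "|standardized mean difference|", y = NULL,
                  colour = NULL)
}
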