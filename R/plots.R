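#' Forest plot of per-SNP causal estimates
#'
#' @param per_snp tibble from [wald_ratios()] (columns `rsid`, `or`,
#'   `ci_low`, `ci_high`).
#' @param pooled optional one-row `mr_estimate` drawn as a reference
#'   line.
#' @return a ggplot object.
#' @export
plot_forest <- function(per_snp, pooled = NULL) {
  p <- ggplot2::ggplot(per_snp,
                       ggplot2::aes(x = .data$or,
                                    y = stats::reorder(.data$rsid, .data$or))) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(pooled)) {
    p <- p + ggplot2::geom_vline(xintercept = pooled$or, colour = "red")
  }
  p
}

#' Leave-one-out sensitivity plot
#'
#' @param loo tibble from [leave_one_out()].
#' @param full optional full-set `mr_estimate` drawn as a reference
#'   line.
#' @return a ggplot object.
#' @export
plot_leave_one_out <- function(loo, full = NULL) {
  p <- ggplot2::ggplot(loo, ggplot2::aes(x = .data$or, y = .data$excluded_rsid)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio omitting the SNP (95% CI)",
                  y = "Excluded SNP") +
    ggplot2::theme_minimal()
  if (!is.null(full)) {
    p <- p + ggplot2::geom_vline(xintercept = full$or, colour = "red")
  }
  p
}

#' Method-comparison plot of pooled estimates
#'
#' One row per estimation method (IVW, Egger, weighted median,
#' multivariable MR, observational meta-analysis), odds ratio with 95%
#' CI.
#'
#' @param estimates a tibble of `mr_estimate` rows (e.g.
#'   `report$estimates`), optionally including the observational pooled
#'   row.
#' @param scale which scale to show (default `"users_vs_nonusers"`).
#' @return a ggplot object.
#' @export
plot_estimate_comparison <- function(estimates, scale = "users_vs_nonusers") {
  df <- estimates[estimates$scale == scale, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$method)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mr_report <- function(object, ...) {
  est <- object$estimates
  if (!is.null(object$meta_obs)) {
    est <- dplyr::bind_rows(est, tidy(object$meta_obs))
  }
  plot_estimate_comparison(est)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
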