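# ggplot2 views of sweep results: metric-vs-size curves, the LOO/LMO
# overlay on the n_fitted axis, and intra-class rank-correlation curves.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot summary validation curves of a sweep
#'
#' Median (or chosen statistic) of each validation metric against sample
#' size, one panel per metric, coloured by model spec and linetype by
#' randomization scheme.
#'
#' @param object A [run_sweep()] result.
#' @param metrics Metrics to show (default the six standard ones present).
#' @param statistic Passed to [summarize_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, metrics = NULL,
                                  statistic = "median", ...) {
  s <- summarize_sweep(object, statistic)
  if (!is.null(metrics)) s <- dplyr::filter(s, .data$metric %in% metrics)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$size, y = .data$value,
                                  colour = .data$spec,
                                  linetype = .data$rand_scheme)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "sample size", y = NULL,
                  colour = "model", linetype = "scheme") +
    ggplot2::theme_bw()
}

#' Plot the LOO/LMO overlay on the fitted-cases axis
#'
#' Draws the median Q2 cross-validation curves against `n_fitted` (the
#' number of cases fitted per sub-model): on this axis the m-fold curves
#' collapse onto the leave-one-out curve.
#'
#' @param cv_curves Output of [summarize_cv_curves()].
#' @return A ggplot object.
#' @export
plot_overlay <- function(cv_curves) {
  ggplot2::ggplot(cv_curves,
                  ggplot2::aes(x = .data$n_fitted, y = .data$q2,
                               colour = .data$scheme)) +
    ggplot2::geom_line(data = ~dplyr::filter(.x, .data$scheme == "loo")) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "cases fitted per sub-model (n_fitted)",
                  y = expression(Q^2), colour = "CV scheme") +
    ggplot2::theme_bw()
}

#' Plot intra-class rank-correlation curves
#'
#' One curve per metric pair: the within-class Spearman correlation of the
#' pair against sample size.
#'
#' @param curves Output of [intraclass_rank_curves()].
#' @return A ggplot object.
#' @export
plot_rank_curves <- function(curves) {
  curves$pair <- paste(curves$metric_a, curves$metric_b, sep = "/")
  ggplot2::ggplot(dplyr::filter(curves, !.data$degenerate),
                  ggplot2::aes(x = .data$size, y = .data$rho,
                               colour = .data$pair)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sample size", y = "intra-class Spearman rho",
                  colour = "metric pair") +
    ggplot2::theme_bw()
}
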