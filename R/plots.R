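#' Cost-effectiveness plane scatter of a PSA cloud
#'
#' Incremental effectiveness against incremental cost, one point per
#' Monte-Carlo iteration, with the willingness-to-pay threshold drawn as a
#' line through the origin (points below the line are cost-effective).
#'
#' @param cloud A `cea_psa` tibble (or data frame with `delta_effect` and
#'   `delta_cost` columns).
#' @param threshold Willingness-to-pay threshold (USD/QALY); defaults to
#'   the cloud's `threshold` attribute.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(cloud, threshold = attr(cloud, "threshold")) {
  p <- ggplot2::ggplot(cloud,
                       ggplot2::aes(x = .data$delta_effect,
                                    y = .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "Incremental effectiveness (QALY)",
                  y = "Incremental cost (USD)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_abline(slope = threshold, intercept = 0,
                                  linetype = "dashed", colour = "firebrick")
  }
  p
}

#' @method autoplot cea_psa
#' @export
autoplot.cea_psa <- function(object, ...) plot_ce_plane(object, ...)

#' Tornado diagram of a one-way sensitivity analysis
#'
#' Horizontal bars spanning each parameter's ICER at its low and high
#' value, ordered by spread, with the base-case ICER as a vertical line.
#'
#' @param tornado A `cea_tornado` tibble from [one_way_dsa()].
#' @param top Show at most this many parameters (default all).
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, top = nrow(tornado)) {
  df <- utils::head(tornado, top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  base_icer <- attr(tornado, "icer_base")
  p <- ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::labs(x = "ICER (USD/QALY)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
  if (!is.null(base_icer)) {
    p <- p + ggplot2::geom_vline(xintercept = base_icer,
                                 linetype = "dashed")
  }
  p
}

#' @method autoplot cea_tornado
#' @export
autoplot.cea_tornado <- function(object, ...) plot_tornado(object, ...)

#' Cost-effectiveness acceptability curve plot
#'
#' @param curve A `cea_ceac` tibble from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$threshold,
                                      y = .data$probability_acceptable)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay threshold (USD/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' @method autoplot cea_ceac
#' @export
autoplot.cea_ceac <- function(object, ...) plot_ceac(object)
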