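#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot world price trajectories
#'
#' One line per crop of the world clearing price over the projection
#' horizon.
#'
#' @param object A `csa_states` tibble from [project_market()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.csa_states <- function(object, ...) {
  prices <- dplyr::distinct(object, .data$year, .data$crop, .data$price)
  ggplot2::ggplot(prices,
                  ggplot2::aes(.data$year, .data$price,
                               colour = .data$crop)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "world price (relative to base year)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a scenario summary as mean-and-range whiskers
#'
#' Points at the climate-average value with whiskers spanning the
#' climate x tailoring range, facetted by metric.
#'
#' @param object A `csa_summary` from [summarize_runs()].
#' @param metrics Optional character vector of metrics to keep.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.csa_summary <- function(object, metrics = NULL, ...) {
  dat <- object
  if (!is.null(metrics)) {
    dat <- dplyr::filter(dat, .data$metric %in% metrics)
  }
  ggplot2::ggplot(dat,
                  ggplot2::aes(.data$scenario, .data$mean)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$min, ymax = .data$max)
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean (min-max range)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the distribution of adopted yield gains by practice
#'
#' @param decisions Output of [decide_cells()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_adoption_gains <- function(decisions, ...) {
  dat <- dplyr::filter(decisions, .data$chosen != "retain_current")
  ggplot2::ggplot(dat,
                  ggplot2::aes(.data$yield_delta, fill = .data$chosen)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.8,
                            position = "identity") +
    ggplot2::labs(x = "adopted yield gain (fraction)", y = "cells",
                  fill = "practice") +
    ggplot2::theme_minimal()
}
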