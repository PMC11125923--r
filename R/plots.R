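#' Plot methods
#'
#' ggplot2 visualizations for the main result types: the simulated canopy
#' trajectory, the assimilation fitness trace, the RMSEP component-choice
#' curve, and the gray histogram with its Otsu threshold.
#'
#' @param object,x the object to plot.
#' @param ... unused.
#' @return a ggplot.
#' @name aquapso-plots
NULL

#' @rdname aquapso-plots
#' @export
autoplot.aqp_sim <- function(object, ...) {
  ggplot2::ggplot(object$daily, ggplot2::aes(x = .data$day, y = .data$cc)) +
    ggplot2::geom_line(color = "forestgreen") +
    ggplot2::labs(x = "day", y = "canopy coverage (%)",
                  title = "Simulated canopy-cover development") +
    ggplot2::ylim(0, 100)
}

#' @rdname aquapso-plots
#' @export
autoplot.aqp_assimilation <- function(object, ...) {
  ggplot2::ggplot(object$fitness_trace,
                  ggplot2::aes(x = .data$iteration, y = .data$gbest_f)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "iteration", y = paste0("best fitness (",
                                              object$config$variant, ")"),
                  title = "Particle-swarm fitness trace")
}

#' @rdname aquapso-plots
#' @param rmsep result of [rmsep_curve()].
#' @export
plot_rmsep <- function(rmsep) {
  ggplot2::ggplot(rmsep$curve, ggplot2::aes(x = .data$k, y = .data$rmsep)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = rmsep$selected, linetype = 2) +
    ggplot2::labs(x = "number of components", y = "RMSEP (LOO)",
                  title = "PLSR component selection")
}

#' @rdname aquapso-plots
#' @param hist 256 gray-level counts; `threshold` an optional cut to mark.
#' @param threshold optional threshold to draw.
#' @export
plot_gray_histogram <- function(hist, threshold = NULL) {
  df <- tibble::tibble(gray = 0:255, count = hist)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$gray, y = .data$count)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "gray level", y = "pixel count",
                  title = "Gray-level frequency distribution")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, color = "red",
                                 linetype = 2)
  }
  p
}
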