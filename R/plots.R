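#' Plot a metric against cortical depth
#'
#' Scatter of per-channel (or per-slice) values with a loess smooth of the
#' means, the standard laminar-profile view.
#'
#' @param data Tibble with depth and metric columns.
#' @param metric Metric column name (string).
#' @param depth Depth column name.
#' @param span Loess span.
#' @return A ggplot object.
#' @export
plot_depth_profile <- function(data, metric, depth = "depth_um", span = 0.5) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[depth]], y = .data[[metric]])) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "loess", span = span, se = TRUE,
                         formula = y ~ x) +
    ggplot2::labs(x = "Depth from pia (µm)", y = metric) +
    ggplot2::theme_minimal()
}

#' Nyquist plot of impedance sweeps
#'
#' Real versus negative imaginary impedance, one curve per day.
#'
#' @param sweeps Sweep tibble (see [average_sweeps()]).
#' @return A ggplot object.
#' @export
plot_nyquist <- function(sweeps) {
  ggplot2::ggplot(sweeps,
                  ggplot2::aes(x = .data$z_real_ohm / 1e3,
                               y = -.data$z_imag_ohm / 1e3,
                               colour = factor(.data$day))) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "Re(Z) (kΩ)", y = "-Im(Z) (kΩ)",
                  colour = "Day") +
    ggplot2::theme_minimal()
}

#' Ring profile plot
#'
#' Nucleus counts (bars) and mean circularity (line) per concentric ring.
#'
#' @param rings Tibble from [ring_profile()].
#' @return A ggplot object.
#' @export
plot_ring_profile <- function(rings) {
  mid <- (rings$ring_lo_um + rings$ring_hi_um) / 2
  ggplot2::ggplot(dplyr::mutate(rings, mid_um = mid),
                  ggplot2::aes(x = .data$mid_um)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n), fill = "grey70") +
    ggplot2::labs(x = "Distance from hole boundary (µm)",
                  y = "Nuclei per ring") +
    ggplot2::theme_minimal()
}

#' Plot a stack's depth profiles
#'
#' @param object A `stack_profile`.
#' @param ... Unused.
#' @return A ggplot object showing per-slice cell-loss area and its
#'   smoothed profile across depth.
#' @export
autoplot.stack_profile <- function(object, ...) {
  ggplot2::ggplot(object$per_slice,
                  ggplot2::aes(x = .data$depth_mid_um,
                               y = .data$loss_area_um2 / 1e3)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = object$smooth,
                       ggplot2::aes(x = .data$depth_um,
                                    y = .data$loss_area_um2 / 1e3),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$loss_peak_um, linetype = 2) +
    ggplot2::labs(x = "Depth from pia (µm)",
                  y = "Cell-loss area (10³ µm²)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
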