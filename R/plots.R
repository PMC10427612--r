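#' Plot a free-energy landscape
#'
#' Free energy (in \eqn{k_B T}) against cluster size on a log size axis,
#' with the bootstrap confidence ribbon when present; censored bins are
#' drawn as open points.
#'
#' @param object A `free_energy_landscape`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.free_energy_landscape <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[is.finite(d$dG_kT), ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$dG_kT))
  if (all(c("ci_low", "ci_high") %in% names(d)) && any(is.finite(d$ci_low))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      fill = "grey70", alpha = 0.5)
  }
  p +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$censored), size = 1.8) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cluster size n (molecules)",
                  y = expression(Delta * G[n] ~ "(" * k[B] * T * ")")) +
    ggplot2::theme_minimal()
}

#' Plot an MSD curve
#'
#' Mean squared displacement against lag time on log-log axes, with guide
#' lines for free (slope 1) diffusion.
#'
#' @param object An `msd_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msd_curve <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lag_s, y = .data$msd_um2)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag time (s)",
                  y = expression("MSD (" * mu * m^2 * ")")) +
    ggplot2::theme_minimal()
}

#' Plot a fitted photobleaching trace
#'
#' Raw intensity with the fitted piecewise-constant staircase overlaid.
#'
#' @param object A `step_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.step_fit <- function(object, ...) {
  d <- tibble::tibble(frame = seq_along(object$trace),
                      intensity = object$trace, fitted = object$fitted)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$intensity), colour = "grey50") +
    ggplot2::geom_step(ggplot2::aes(y = .data$fitted), colour = "red",
                       linewidth = 0.7) +
    ggplot2::labs(x = "frame", y = "intensity (a.u.)",
                  subtitle = sprintf("%d bleaching steps", object$n_steps)) +
    ggplot2::theme_minimal()
}

#' Plot cluster tracks in the image plane
#'
#' Centroid trajectories coloured by track, with point size proportional to
#' cluster area; y is flipped to match image coordinates.
#'
#' @param tracks A track table.
#' @return A ggplot.
#' @export
plot_tracks <- function(tracks) {
  stopifnot(all(c("track_id", "x_um", "y_um") %in% names(tracks)))
  ggplot2::ggplot(tracks,
                  ggplot2::aes(x = .data$x_um, y = .data$y_um,
                               group = .data$track_id,
                               colour = factor(.data$track_id))) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::geom_point(ggplot2::aes(size = .data$area_um2), alpha = 0.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::coord_equal() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = expression(x ~ "(" * mu * m * ")"),
                  y = expression(y ~ "(" * mu * m * ")"),
                  size = expression("area (" * mu * m^2 * ")")) +
    ggplot2::theme_minimal()
}
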