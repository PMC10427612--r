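#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a diffusion fit
#'
#' One row per parameter (`D`, `alpha`).
#'
#' @param x A `diffusion_fit`.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate`.
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(term = c("D", "alpha"), estimate = c(x$D, x$alpha))
}

#' @rdname tidy.diffusion_fit
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(D = x$D, alpha = x$alpha, classification = x$classification,
                 model = x$model, n_lags = x$n_lags)
}

#' Tidy an initial-scaling fit
#'
#' @param x A `scaling_fit`.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate` rows for the exponent and
#'   amplitude.
#' @export
tidy.scaling_fit <- function(x, ...) {
  tibble::tibble(term = c("beta", "amplitude"),
                 estimate = c(x$beta, x$amplitude))
}

#' @rdname tidy.scaling_fit
#' @export
glance.scaling_fit <- function(x, ...) {
  tibble::tibble(beta = x$beta, amplitude = x$amplitude,
                 plateau_onset = x$plateau_onset, n_bins = x$n_bins,
                 r_squared = x$r_squared)
}

#' Tidy a dense-phase density estimate
#'
#' @param x A `density_estimate`.
#' @param ... Unused.
#' @return `tidy()`: per-region step counts and areas. `glance()`: one row
#'   with `rho`, `se`, `n_regions`, `total_steps`, `total_area_um2`.
#' @export
tidy.density_estimate <- function(x, ...) x$regions

#' @rdname tidy.density_estimate
#' @export
glance.density_estimate <- function(x, ...) {
  tibble::tibble(rho = x$rho, se = x$se, n_regions = x$n_regions,
                 total_steps = x$total_steps, total_area_um2 = x$total_area_um2)
}

#' Tidy a step fit
#'
#' @param x A `step_fit`.
#' @param ... Unused.
#' @return `tidy()`: the fitted steps (frame, levels, size). `glance()`:
#'   one row with the downward/upward step counts and the quality ratio.
#' @export
tidy.step_fit <- function(x, ...) x$steps

#' @rdname tidy.step_fit
#' @export
glance.step_fit <- function(x, ...) {
  tibble::tibble(n_steps = x$n_steps, n_steps_up = x$n_steps_up,
                 quality = x$quality)
}

#' Tidy a lag-time summary
#'
#' @param x A `lag_summary`.
#' @param ... Unused.
#' @return `glance()`: one row with the lag-time mean, coefficient of
#'   variation and censoring count.
#' @export
glance.lag_summary <- function(x, ...) {
  tibble::tibble(mean_lag_s = attr(x, "mean_lag_s"), cv = attr(x, "cv"),
                 n_cells = nrow(x), n_censored = attr(x, "n_censored"))
}
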