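#' Render a simulated cluster movie as a 16-bit image stack
#'
#' Draws each cluster as a filled disc whose area follows the fixed
#' dense-phase density: `area = n_true * label_fraction / rho` square microns
#' (the labelled-molecule density in the dense phase is `rho` in expectation,
#' so the area-based calibration `area * rho / f_label` inverts it exactly).
#' The disc's brightness is set by the labelled count `n_gfp`: labelling
#' stochasticity shows up in intensity, not in the footprint. The photon
#' image is convolved with a Gaussian PSF,
#' applies exponential photobleaching, adds a constant background, then
#' Poisson shot noise and Gaussian read noise, and quantises to 16 bits.
#' Sub-resolution clusters (disc radius below half a pixel) are deposited
#' into the nearest pixel before blurring.
#'
#' @param sim A `cluster_sim` from [simulate_cluster_dynamics()].
#' @param config Optional override of `sim$config`.
#' @return An integer array `height x width x n_frames` of class
#'   `cluster_movie`, with the config attached as attribute `config`.
#' @examples
#' sim <- simulate_cluster_dynamics(sim_config(n_frames = 3, n_clusters_init = 3,
#'                                             field_size = c(64, 64), seed = 3))
#' mov <- render_movie(sim)
#' dim(mov)
#' @export
render_movie <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "cluster_sim"))
  set.seed(config$seed + 1L) # independent of the dynamics stream
  W <- config$field_size[1]; H <- config$field_size[2]
  px <- config$pixel_size
  sigma_px <- config$psf_sigma / px
  stack <- array(0L, dim = c(H, W, config$n_frames))

  field_area_um2 <- W * H * px^2
  max_area <- max(sim$truth$n_true) * config$label_fraction / config$gfp_density_rho
  if (max_area > field_area_um2) stop("cluster area exceeds the field; reject config", call. = FALSE)

  by_frame <- split(sim$truth, sim$truth$frame)
  for (f in seq_len(config$n_frames)) {
    amp <- matrix(0, H, W)
    fr <- by_frame[[as.character(f)]]
    if (!is.null(fr) && nrow(fr) > 0L) {
      for (k in seq_len(nrow(fr))) {
        ng <- fr$n_gfp_true[k]
        if (ng <= 0) next
        photons <- ng * config$poisson_gain
        area_um2 <- fr$n_true[k] * config$label_fraction / config$gfp_density_rho
        # pixel centres at 0-based index * pixel size
        cx <- fr$x_um[k] / px; cy <- fr$y_um[k] / px
        r_px <- sqrt(area_um2 / pi) / px
        if (r_px < 0.5) {
          i <- pmin(pmax(round(cy), 0), H - 1); j <- pmin(pmax(round(cx), 0), W - 1)
          amp[i + 1, j + 1] <- amp[i + 1, j + 1] + photons
        } else {
          j0 <- max(floor(cx - r_px - 1), 0); j1 <- min(ceiling(cx + r_px + 1), W - 1)
          i0 <- max(floor(cy - r_px - 1), 0); i1 <- min(ceiling(cy + r_px + 1), H - 1)
          jj <- j0:j1; ii <- i0:i1
          dist2 <- outer((ii - cy)^2, (jj - cx)^2, "+")
          disc <- dist2 <= r_px^2
          npix <- sum(disc)
          if (npix == 0L) { # degenerate: all mass to nearest pixel
            i <- pmin(pmax(round(cy), 0), H - 1); j <- pmin(pmax(round(cx), 0), W - 1)
            amp[i + 1, j + 1] <- amp[i + 1, j + 1] + photons
          } else {
            amp[ii + 1, jj + 1] <- amp[ii + 1, jj + 1] + disc * (photons / npix)
          }
        }
      }
    }
    if (sigma_px > 0) amp <- gaussian_blur(amp, sigma_px)
    lam <- amp * exp(-config$photobleach_rate * (f - 1)) + config$background
    noisy <- if (isTRUE(config$shot_noise)) {
      stats::rpois(length(lam), lam) + stats::rnorm(length(lam), 0, config$read_noise_sd)
    } else lam
    stack[, , f] <- matrix(as.integer(pmin(pmax(round(noisy), 0), 65535L)), H, W)
  }
  structure(stack, class = c("cluster_movie", "array"), config = config)
}

# Separable Gaussian blur with reflective boundaries (flux-preserving in the
# interior). Kernel truncated at 4 sigma.
gaussian_blur <- function(m, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  blur1 <- function(mat) { # along rows (dimension 1)
    n <- nrow(mat)
    idx <- outer(seq_len(n), -half:half, "+") - 1L # 0-based, may be far out
    if (n > 1L) {
      per <- 2L * (n - 1L)
      idx <- abs(idx) %% per
      idx <- ifelse(idx > n - 1L, per - idx, idx)
    } else {
      idx[] <- 0L
    }
    out <- matrix(0, n, ncol(mat))
    for (t in seq_along(k)) out <- out + k[t] * mat[idx[, t] + 1L, , drop = FALSE]
    out
  }
  t(blur1(t(blur1(m))))
}

#' @export
print.cluster_movie <- function(x, ...) {
  d <- dim(x)
  cat("<cluster_movie>", d[1], "x", d[2], "px,", d[3], "frames, 16-bit\n")
  invisible(x)
}
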