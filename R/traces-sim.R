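#' Simulate a stepwise photobleaching trace
#'
#' Produces a monotone non-increasing intensity staircase: `n_steps` downward
#' steps of height `step_height` at random positions, plus Gaussian noise.
#' Dwell times between bleach events follow the physics of independent
#' fluorophores: with `k` unbleached fluorophores remaining, the time to the
#' next event is exponential with rate `k * bleach_rate` (per frame), so
#' early steps come faster than late ones.
#'
#' @param n_steps Number of fluorophores (downward steps); may be 0.
#' @param step_height Intensity drop per fluorophore (arbitrary units).
#' @param noise_sd Gaussian noise standard deviation; signal-to-noise ratio
#'   is `step_height / noise_sd`.
#' @param bleach_rate Per-fluorophore bleach probability per frame; sets the
#'   dwell-time scale (`dwell_frames = 1 / bleach_rate` on average for the
#'   last fluorophore).
#' @param min_dwell Minimum frames between consecutive steps (and before the
#'   first). Camera integration merges faster double-bleaches into one larger
#'   step, so traces are generated with resolvable plateaus.
#' @param baseline Intensity after all fluorophores have bleached.
#' @param tail_frames Frames appended after the final step.
#' @param n_frames Optional fixed trace length; dwells are then drawn
#'   uniformly instead of exponentially so all steps fit.
#' @param seed Optional integer seed.
#' @return An object of class `bleach_trace`: a tibble (`frame`,
#'   `intensity`) with attributes `true_steps` (frames at which the level
#'   drops, i.e. last frame of the higher plateau), `true_levels`, and
#'   `n_steps_true`.
#' @examples
#' tr <- simulate_bleach_trace(3, noise_sd = 0, seed = 1)
#' attr(tr, "n_steps_true")
#' @export
simulate_bleach_trace <- function(n_steps, step_height = 100, noise_sd = 0,
                                  bleach_rate = 0.02, min_dwell = 5,
                                  baseline = 0,
                                  tail_frames = 30, n_frames = NULL,
                                  seed = NULL) {
  stopifnot(n_steps >= 0, step_height > 0, noise_sd >= 0, bleach_rate > 0,
            min_dwell >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- as.integer(n_steps)

  if (n_steps == 0L) {
    len <- if (is.null(n_frames)) tail_frames else n_frames
    step_frames <- integer(0)
  } else if (is.null(n_frames)) {
    dwell <- min_dwell + stats::rgeom(n_steps, pmin(bleach_rate * n_steps:1, 0.5))
    step_frames <- cumsum(dwell)
    len <- step_frames[n_steps] + tail_frames
  } else {
    stopifnot(n_frames > (min_dwell + 1) * n_steps)
    gaps <- stats::rmultinom(1, n_frames - 1L - min_dwell * n_steps,
                             rep(1, n_steps + 1L))[, 1]
    step_frames <- cumsum(gaps[seq_len(n_steps)] + min_dwell)
    len <- n_frames
  }

  levels <- baseline + step_height * (n_steps:0)
  drops_after <- c(step_frames, len)
  ideal <- rep(levels, times = diff(c(0L, drops_after)))
  intensity <- ideal + stats::rnorm(len, 0, noise_sd)

  structure(
    tibble::tibble(frame = seq_len(len), intensity = intensity),
    true_steps = step_frames,
    true_levels = levels,
    n_steps_true = n_steps,
    class = c("bleach_trace", "tbl_df", "tbl", "data.frame")
  )
}

#' Simulate fixed-cell cluster regions with photobleaching traces
#'
#' Emulates the fixed-cell calibration experiment: a set of small cluster
#' regions, each holding a known number of labelled molecules, bleached under
#' constant illumination. Region areas follow the dense-phase density
#' (`area = n_gfp / rho`), so pooling fitted step counts over summed areas
#' recovers `rho`.
#'
#' @param n_regions Number of cluster regions.
#' @param rho Dense-phase labelled-molecule density (um^-2).
#' @param n_gfp_range Inclusive range the per-region molecule number is drawn
#'   from (uniformly).
#' @param snr Step height over noise standard deviation.
#' @param step_height Intensity per molecule (arbitrary units).
#' @param bleach_rate Per-fluorophore bleach probability per frame.
#' @param seed Integer seed.
#' @return A tibble with one row per region: `region_id`, `area_um2`,
#'   `n_gfp_true`, and a list-column `trace` of `bleach_trace` objects.
#' @export
simulate_fixed_cell_traces <- function(n_regions = 50, rho = 29,
                                       n_gfp_range = c(3L, 15L),
                                       snr = 5, step_height = 100,
                                       bleach_rate = 0.02, seed = 1L) {
  stopifnot(n_regions >= 1, rho > 0, snr > 0)
  set.seed(seed)
  n_gfp <- sample(seq(n_gfp_range[1], n_gfp_range[2]), n_regions, replace = TRUE)
  traces <- purrr::map(n_gfp, function(k) {
    simulate_bleach_trace(k, step_height = step_height,
                          noise_sd = step_height / snr,
                          bleach_rate = bleach_rate)
  })
  tibble::tibble(region_id = seq_len(n_regions),
                 area_um2 = n_gfp / rho,
                 n_gfp_true = n_gfp,
                 trace = traces)
}

#' Simulate a 2-D single-particle track with anomalous diffusion
#'
#' Generates positions whose time-averaged mean squared displacement follows
#' \eqn{\langle r^2\rangle = 4 D t^\alpha} in expectation. For
#' \eqn{\alpha = 1} increments are independent Gaussians; for other
#' \eqn{\alpha \in (0, 2)} each coordinate is fractional Brownian motion with
#' Hurst index \eqn{H = \alpha/2}, built from fractional Gaussian noise by the
#' Hosking (Durbin--Levinson) recursion; \eqn{\alpha = 2} is the deterministic
#' ballistic limit with speed \eqn{2\sqrt{D}} in a random direction.
#'
#' @param D Generalised diffusion coefficient (um^2 s^-alpha).
#' @param alpha Anomalous exponent in (0, 2].
#' @param dt Frame interval (s).
#' @param n_steps Number of steps (the track has `n_steps + 1` positions).
#' @param seed Optional integer seed.
#' @return A tibble: `frame`, `time_s`, `x_um`, `y_um`.
#' @examples
#' tr <- simulate_track(D = 0.1, alpha = 1, dt = 10, n_steps = 50, seed = 1)
#' @export
simulate_track <- function(D, alpha = 1, dt = 1, n_steps = 100, seed = NULL) {
  stopifnot(D >= 0, alpha > 0, alpha <= 2, dt > 0, n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  tt <- (0:n_steps) * dt
  if (D == 0) {
    x <- y <- numeric(n_steps + 1)
  } else if (alpha == 2) {
    th <- stats::runif(1, 0, 2 * pi)
    v <- 2 * sqrt(D)
    x <- v * cos(th) * tt
    y <- v * sin(th) * tt
  } else {
    scale <- sqrt(2 * D) * dt^(alpha / 2)
    x <- c(0, cumsum(scale * fgn_hosking(n_steps, alpha / 2)))
    y <- c(0, cumsum(scale * fgn_hosking(n_steps, alpha / 2)))
  }
  tibble::tibble(frame = 0:n_steps, time_s = tt, x_um = x, y_um = y)
}

# Unit-variance fractional Gaussian noise of length n with Hurst index H,
# by the Hosking / Durbin-Levinson recursion (exact covariance, O(n^2)).
fgn_hosking <- function(n, H) {
  if (abs(H - 0.5) < 1e-12) return(stats::rnorm(n))
  k <- 0:n
  gam <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  X <- numeric(n)
  v <- gam[1]
  X[1] <- stats::rnorm(1, 0, sqrt(v))
  phi <- numeric(0)
  for (i in seq_len(n - 1)) {
    a <- if (i == 1) gam[2] / gam[1] else
      (gam[i + 1] - sum(phi * gam[i:2])) / v
    phi <- c(phi - a * rev(phi), a)
    v <- v * (1 - a^2)
    X[i + 1] <- stats::rnorm(1, sum(phi * X[i:1]), sqrt(max(v, 0)))
  }
  X
}
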