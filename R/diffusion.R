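#' Time-averaged mean squared displacement of one track
#'
#' For each lag \eqn{\tau}, averages \eqn{|r(t+\tau) - r(t)|^2} over all
#' ordered pairs within the track. Lags run from 1 to a quarter of the track
#' length (short lags have many pairs and small estimator variance; long
#' lags are unreliable for a single track).
#'
#' @param track Tibble with `x_um`, `y_um` and either `time_s` or `frame`
#'   (equally spaced).
#' @param dt Frame interval (s); inferred from `time_s` when present.
#' @param max_lag_frac Longest lag as a fraction of track length.
#' @param min_length Minimum number of positions; shorter tracks error.
#' @return An object of class `msd_curve`: tibble `lag` (frames), `lag_s`,
#'   `msd_um2`, `n_pairs`.
#' @examples
#' tr <- simulate_track(D = 0.05, dt = 10, n_steps = 60, seed = 1)
#' msd(tr)
#' @export
msd <- function(track, dt = NULL, max_lag_frac = 0.25, min_length = 10) {
  stopifnot(is.data.frame(track), all(c("x_um", "y_um") %in% names(track)))
  n <- nrow(track)
  if (n < min_length) {
    stop(sprintf("track too short for MSD: %d < %d positions", n, min_length),
         call. = FALSE)
  }
  if (is.null(dt)) {
    dt <- if ("time_s" %in% names(track)) {
      d <- diff(track$time_s)
      stats::median(d)
    } else 1
  }
  x <- track$x_um; y <- track$y_um
  lags <- seq_len(max(1L, floor(max_lag_frac * n)))
  out <- purrr::map_dfr(lags, function(L) {
    dx <- x[(1 + L):n] - x[1:(n - L)]
    dy <- y[(1 + L):n] - y[1:(n - L)]
    tibble::tibble(lag = L, lag_s = L * dt,
                   msd_um2 = mean(dx^2 + dy^2), n_pairs = n - L)
  })
  structure(out, dt = dt,
            class = c("msd_curve", "tbl_df", "tbl", "data.frame"))
}

#' Fit a diffusion law to an MSD curve
#'
#' Free diffusion: least-squares slope of MSD against lag time through the
#' origin, \eqn{D = slope / 4}. Generalised: linear fit of
#' \eqn{\log MSD = \log 4D + \alpha \log t}, giving the anomalous exponent
#' \eqn{\alpha} and generalised coefficient \eqn{D}. Motion is classified
#' sub-diffusive when \eqn{\alpha < 1 - tol}, directed when
#' \eqn{\alpha > 1 + tol}, free otherwise.
#'
#' @param msd_curve An [msd()] result (or tibble with `lag_s`, `msd_um2`).
#' @param model `"free"` or `"generalized"`.
#' @param tol Classification tolerance band around \eqn{\alpha = 1}.
#' @return An object of class `diffusion_fit`: list with `D` (um^2 s^-1 for
#'   the free fit; um^2 s^-alpha generalised), `alpha`, `classification`,
#'   `model`, `n_lags`.
#' @examples
#' curve <- tibble::tibble(lag_s = 1:10, msd_um2 = 4 * 0.5 * (1:10))
#' fit_diffusion(curve, "free")$D
#' @export
fit_diffusion <- function(msd_curve, model = c("free", "generalized"),
                          tol = 0.2) {
  model <- match.arg(model)
  stopifnot(is.data.frame(msd_curve),
            all(c("lag_s", "msd_um2") %in% names(msd_curve)))
  d <- msd_curve[is.finite(msd_curve$msd_um2), ]
  if (model == "free") {
    if (nrow(d) < 4L) stop("need at least 4 lag points", call. = FALSE)
    slope <- sum(d$msd_um2 * d$lag_s) / sum(d$lag_s^2)
    D <- slope / 4
    alpha <- 1
  } else {
    d <- d[d$msd_um2 > 0, ]
    if (nrow(d) < 4L) stop("need at least 4 positive lag points", call. = FALSE)
    fit <- stats::lm(log(msd_um2) ~ log(lag_s), data = d)
    co <- stats::coef(fit)
    alpha <- unname(co[2])
    D <- exp(unname(co[1])) / 4
  }
  cls <- if (model == "free") "free" else if (alpha < 1 - tol) "sub"
         else if (alpha > 1 + tol) "directed" else "free"
  structure(
    list(D = D, alpha = alpha, classification = cls, model = model,
         n_lags = nrow(d)),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit:%s> D = %.4g um^2 s^-%s, alpha = %.3f (%s)\n",
              x$model, x$D, if (x$model == "free") "1" else "alpha",
              x$alpha, x$classification))
  invisible(x)
}

#' Per-track diffusion fits for a track table
#'
#' Computes the time-averaged MSD and the generalised diffusion fit for
#' every track long enough; shorter tracks are excluded and listed in the
#' `excluded` attribute with the reason.
#'
#' @param tracks Track table (`track_id`, `x_um`, `y_um`, `time_s`;
#'   optionally `cell_id`).
#' @param min_length Minimum track length (frames).
#' @param tol Classification tolerance.
#' @return A tibble: `cell_id` (if present), `track_id`, `n_frames`, `D`,
#'   `alpha`, `classification`; excluded tracks in `attr(,"excluded")`.
#' @export
fit_tracks_diffusion <- function(tracks, min_length = 10, tol = 0.2) {
  stopifnot(all(c("track_id", "x_um", "y_um") %in% names(tracks)))
  grp <- intersect(c("cell_id", "track_id"), names(tracks))
  nested <- tracks |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    tidyr::nest() |>
    dplyr::ungroup()
  res <- purrr::map(nested$data, function(tr) {
    if (nrow(tr) < min_length) {
      return(list(ok = FALSE, reason = sprintf("track length %d < %d", nrow(tr), min_length)))
    }
    curve <- msd(tr, min_length = min_length)
    fit <- tryCatch(fit_diffusion(curve, "generalized", tol = tol),
                    error = function(e) NULL)
    if (is.null(fit)) return(list(ok = FALSE, reason = "degenerate MSD"))
    list(ok = TRUE, n_frames = nrow(tr), D = fit$D, alpha = fit$alpha,
         classification = fit$classification)
  })
  ok <- vapply(res, `[[`, logical(1), "ok")
  out <- dplyr::bind_cols(
    nested[ok, grp, drop = FALSE],
    purrr::map_dfr(res[ok], function(r) {
      tibble::tibble(n_frames = r$n_frames, D = r$D, alpha = r$alpha,
                     classification = r$classification)
    })
  )
  attr(out, "excluded") <- dplyr::bind_cols(
    nested[!ok, grp, drop = FALSE],
    tibble::tibble(reason = vapply(res[!ok], `[[`, character(1), "reason"))
  )
  out
}
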