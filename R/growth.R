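#' Mean cluster-size gradient of one track
#'
#' \eqn{\nabla_{size}(j) = (1/n_j) \sum_{i=2}^{n_j} |area_i - area_{i-1}|},
#' where \eqn{n_j} is the number of frames over which the cluster was
#' identified. The divisor is \eqn{n_j} (not \eqn{n_j - 1}) even though only
#' \eqn{n_j - 1} differences are summed; the printed convention is kept
#' as-is.
#'
#' @param areas Numeric vector of areas ordered by frame (length >= 2).
#' @return The mean absolute frame-to-frame area change (same units as
#'   `areas` per frame). Zero iff the area is constant.
#' @examples
#' size_gradient(c(1, 3, 2)) # (2 + 1) / 3 = 1
#' @export
size_gradient <- function(areas) {
  areas <- as.numeric(areas)
  if (length(areas) < 2L) return(NA_real_)
  sum(abs(diff(areas))) / length(areas)
}

#' Size gradients and normalised gradients for all tracks
#'
#' Computes the per-track mean size gradient, the track's time-mean area and
#' the normalised gradient (gradient over mean area, per frame). Tracks
#' observed for fewer than 2 frames are dropped.
#'
#' @param tracks Track table (`track_id`, `frame`, `area_um2`, optionally
#'   `cell_id`).
#' @return A tibble: `cell_id` (if present), `track_id`, `n_frames`,
#'   `grad_um2` (um^2 per frame), `mean_area_um2`, `norm_grad` (per frame).
#' @export
size_gradients <- function(tracks) {
  stopifnot(all(c("track_id", "frame", "area_um2") %in% names(tracks)))
  grp <- intersect(c("cell_id", "track_id"), names(tracks))
  tracks |>
    dplyr::arrange(.data$frame) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      grad_um2 = size_gradient(.data$area_um2),
      mean_area_um2 = mean(.data$area_um2),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_frames >= 2L) |>
    dplyr::mutate(norm_grad = .data$grad_um2 / .data$mean_area_um2)
}

#' Dispersion of normalised size gradients across size deciles
#'
#' Groups tracks into deciles of their time-mean area and summarises the
#' normalised gradient per decile. Under coalescence-driven growth the raw
#' gradient grows roughly in proportion to cluster size, so the normalised
#' gradient is flat across deciles (narrow dispersion); under stepwise
#' monomer addition the raw gradient is size-independent and the normalised
#' gradient falls with size.
#'
#' @param tracks Track table.
#' @param n_groups Number of size groups (default 10 deciles; reduced when
#'   there are few tracks).
#' @return A list with `per_track` (the [size_gradients()] tibble with a
#'   `size_group` column), `per_group` (median normalised gradient and IQR
#'   per group) and `dispersion` (IQR/median of group medians).
#' @export
normalized_gradient_distribution <- function(tracks, n_groups = 10) {
  g <- size_gradients(tracks)
  if (nrow(g) == 0L) stop("no track with >= 2 frames", call. = FALSE)
  ng <- max(1L, min(n_groups, nrow(g) %/% 2L))
  g$size_group <- if (ng > 1L) {
    dplyr::ntile(g$mean_area_um2, ng)
  } else rep(1L, nrow(g))
  per_group <- g |>
    dplyr::group_by(.data$size_group) |>
    dplyr::summarise(
      n_tracks = dplyr::n(),
      mean_area_um2 = stats::median(.data$mean_area_um2),
      med_norm_grad = stats::median(.data$norm_grad),
      med_raw_grad = stats::median(.data$grad_um2),
      iqr_norm_grad = stats::IQR(.data$norm_grad),
      .groups = "drop"
    )
  med <- per_group$med_norm_grad
  list(per_track = g, per_group = per_group,
       dispersion = stats::IQR(med) / stats::median(med))
}

#' Ostwald-ripening diagnostic: small-cluster occupancy over time
#'
#' Tracks the probability that a molecule sits in a cluster smaller than the
#' critical size, frame by frame. Under Ostwald ripening, mid-sized clusters
#' dissolve to feed the largest one, transiently raising the small-cluster
#' share; under coalescence-driven growth no such transient appears. The
#' slope of the series is reported with a confidence interval from
#' resampling tracks.
#'
#' @param tracks Calibrated track table (`track_id`, `frame`, `n_total`; use
#'   [calibrate_tracks()] or [truth_to_tracks()] + calibration first).
#' @param critical_n Size threshold in total molecules ("small" means
#'   `n_total < critical_n`).
#' @param frames Optional frame subset (e.g. post-nucleation frames).
#' @param n_boot Bootstrap replicates for the slope CI.
#' @param level Confidence level.
#' @return A list with `series` (tibble: `frame`, `p_small`), `slope` (per
#'   frame), `ci_low`, `ci_high`.
#' @export
ostwald_diagnostic <- function(tracks, critical_n, frames = NULL,
                               n_boot = 1000, level = 0.95) {
  stopifnot(all(c("track_id", "frame", "n_total") %in% names(tracks)))
  d <- if (is.null(frames)) tracks else tracks[tracks$frame %in% frames, ]
  if (nrow(d) == 0L) stop("no observations in the requested frames", call. = FALSE)

  series_of <- function(df) {
    df |>
      dplyr::group_by(.data$frame) |>
      dplyr::summarise(
        p_small = sum(.data$n_total[.data$n_total < critical_n]) /
          sum(.data$n_total),
        .groups = "drop")
  }
  series <- series_of(d)
  slope_of <- function(s) {
    if (nrow(s) < 2L || stats::var(s$frame) == 0) return(NA_real_)
    unname(stats::coef(stats::lm(p_small ~ frame, data = s))[2])
  }
  slope <- slope_of(series)

  ids <- unique(d$track_id)
  reps <- if (length(ids) >= 2L) {
    vapply(seq_len(n_boot), function(b) {
      take <- sample(ids, replace = TRUE)
      # concatenate resampled tracks (duplicates count twice)
      df <- dplyr::bind_rows(lapply(take, function(id) d[d$track_id == id, ]))
      slope_of(series_of(df))
    }, numeric(1))
  } else rep(NA_real_, 2)
  alpha <- (1 - level) / 2
  ci <- stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE)
  list(series = series, slope = slope,
       ci_low = unname(ci[1]), ci_high = unname(ci[2]))
}
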