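#' Identify the condensate lineage in a cell's track table
#'
#' The condensate is the track with the largest final observed area,
#' accepted only if (i) it has clearly outgrown every other track (its
#' running maximum exceeds the largest area any other track reached by at
#' least the factor `dominance`) and (ii) it has not collapsed again (final
#' area at least `retain` of its own running maximum; growth into a
#' condensate is irreversible, transient clusters shrink back). Cells whose
#' largest track fails either test are declared condensate-free: in
#' fluctuating (pre-nucleation or unstressed) cells the largest cluster is
#' statistically indistinguishable from its peers.
#'
#' @param tracks Track table for one cell (`track_id`, `frame`, `area_um2`).
#' @param dominance Required ratio of the candidate's maximum area to the
#'   best of the other tracks.
#' @param retain Required ratio of final to maximum area of the candidate.
#' @return The condensate `track_id`, or `NA` if no track qualifies.
#' @export
identify_condensate <- function(tracks, dominance = 1.3, retain = 0.8) {
  stopifnot(all(c("track_id", "frame", "area_um2") %in% names(tracks)))
  if (nrow(tracks) == 0L) return(NA_integer_)
  smry <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(final_area = .data$area_um2[which.max(.data$frame)],
                     max_area = max(.data$area_um2),
                     last_frame = max(.data$frame), .groups = "drop")
  last_frame <- max(smry$last_frame)
  ending <- smry[smry$last_frame == last_frame, ]
  if (nrow(ending) == 0L) return(NA_integer_)
  cand <- ending[which.max(ending$final_area), ]
  best_other <- max(smry$max_area[smry$track_id != cand$track_id], 0)
  if (cand$final_area >= retain * cand$max_area &&
      (best_other == 0 || cand$max_area >= dominance * best_other)) {
    as.integer(cand$track_id)
  } else {
    NA_integer_
  }
}

#' Per-cell critical cluster size
#'
#' The critical area of a cell is the largest area ever reached by any track
#' that is not part of the condensate lineage, i.e. the size up to which
#' cluster sizes still fluctuate dynamically. Returned both as an area and as
#' a calibrated total molecule count.
#'
#' @param tracks Track table; if it has a `cell_id` column, one row per cell
#'   is returned.
#' @param condensate_id Condensate track id(s); by default found per cell via
#'   [identify_condensate()]. Use `NA` to declare none.
#' @param exclude_tracks Optional track ids to drop as motion artefacts
#'   before taking the maximum.
#' @param model A [calibration_model()] for the molecule-count conversion.
#' @return A tibble: `cell_id`, `condensate_id`, `critical_area_um2`,
#'   `critical_n` (total molecules). `NA` area when no non-condensate track
#'   exists (missing, not zero).
#' @export
critical_size <- function(tracks, condensate_id = NULL, exclude_tracks = NULL,
                          model = calibration_model()) {
  stopifnot(all(c("track_id", "frame", "area_um2") %in% names(tracks)))
  if (!"cell_id" %in% names(tracks)) tracks$cell_id <- 1L
  tracks |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      cond <- if (is.null(condensate_id)) identify_condensate(df) else condensate_id
      rest <- df[!(df$track_id %in% c(cond, exclude_tracks)), ]
      crit <- if (nrow(rest) == 0L) NA_real_ else max(rest$area_um2)
      tibble::tibble(condensate_id = as.integer(cond),
                     critical_area_um2 = crit,
                     critical_n = gfp_to_total(area_to_gfp(crit, model), model))
    }) |>
    dplyr::ungroup()
}

#' Split cluster observations into pre- and post-nucleation ensembles
#'
#' Nucleation is the earliest frame at which the condensate lineage's area
#' exceeds the cell's critical area and never falls below it again.
#' Observations strictly before that frame are pre-nucleation; from that
#' frame on they are post-nucleation. If the condensate never crosses (or
#' there is no condensate), every observation is pre-nucleation and the
#' nucleation frame is `NA`.
#'
#' @param tracks Track table for one cell.
#' @param critical_area The cell's critical area (um^2).
#' @param condensate_id Condensate track id (default: [identify_condensate()]).
#' @return The track table with a `phase` column (`"pre"`/`"post"`) and
#'   attribute `nucleation_frame`.
#' @export
split_pre_post <- function(tracks, critical_area, condensate_id = NULL) {
  stopifnot(is.finite(critical_area))
  if (is.null(condensate_id)) condensate_id <- identify_condensate(tracks)
  nuc <- nucleation_frame(tracks, critical_area, condensate_id)
  out <- dplyr::mutate(tracks,
    phase = ifelse(!is.na(nuc) & .data$frame >= nuc, "post", "pre"))
  attr(out, "nucleation_frame") <- nuc
  out
}

# Earliest frame at which the condensate's area exceeds critical_area and
# stays above it for the rest of the observations.
nucleation_frame <- function(tracks, critical_area, condensate_id) {
  if (is.na(condensate_id)) return(NA_integer_)
  cond <- tracks[tracks$track_id == condensate_id, ]
  cond <- cond[order(cond$frame), ]
  below <- which(cond$area_um2 <= critical_area)
  first_idx <- if (length(below) == 0L) 1L else max(below) + 1L
  if (first_idx > nrow(cond)) return(NA_integer_)
  as.integer(cond$frame[first_idx])
}

#' Monomer-occupancy distribution of a cluster-size ensemble
#'
#' The probability that a randomly chosen molecule resides in a cluster of a
#' given size class: `p(bin) = sum of n over observations in bin / sum of n
#' over all observations`. Size classes are logarithmically spaced integer
#' bins (growth factor `bin_factor`) with geometric-mean centres; small sizes
#' get width-1 bins automatically. Bins with fewer than `min_count`
#' observations are flagged `censored`.
#'
#' @param sizes Cluster sizes (total molecules): a numeric vector, or a data
#'   frame with a column `n` (and optionally `track` used later for
#'   bootstrap grouping).
#' @param bins Optional integer vector of bin breaks (left-open, covering
#'   `min(n)..max(n)`); computed from the data if omitted.
#' @param bin_factor Geometric growth factor of the bin widths.
#' @param min_count Minimum observations for an uncensored bin.
#' @return An object of class `occupancy`: tibble with `n` (bin centre,
#'   geometric mean of the integer sizes in the bin), `p`, `n_obs`, `width`
#'   (number of integer sizes in the bin) and `censored`; bin breaks kept in
#'   attribute `breaks`.
#' @examples
#' monomer_occupancy(c(1, 3))  # p1 = 1/4, p3 = 3/4
#' @export
monomer_occupancy <- function(sizes, bins = NULL, bin_factor = 1.5,
                              min_count = 5) {
  n <- if (is.data.frame(sizes)) sizes$n else as.numeric(sizes)
  if (length(n) == 0L) stop("empty ensemble", call. = FALSE)
  stopifnot(all(n >= 1))
  breaks <- if (is.null(bins)) size_bins(max(n), bin_factor) else as.numeric(bins)
  bin <- findInterval(n, breaks, left.open = FALSE) # breaks[i] <= n < breaks[i+1]
  nb <- length(breaks) - 1L
  mass <- rowsum_vec(n, pmin(bin, nb), nb)
  cnt <- tabulate(pmin(bin, nb), nb)
  lo <- ceiling(breaks[-length(breaks)])
  hi <- ceiling(breaks[-1]) - 1
  hi[length(hi)] <- max(hi[length(hi)], ceiling(max(n)))
  centre <- exp((log(pmax(lo, 1)) + log(pmax(hi, 1))) / 2)
  width <- pmax(hi - lo + 1, 1)
  out <- tibble::tibble(
    n = centre, p = mass / sum(mass), n_obs = cnt, width = width,
    censored = cnt < min_count
  )
  structure(out, breaks = breaks,
            class = c("occupancy", "tbl_df", "tbl", "data.frame"))
}

# Integer bin breaks 1, 2, 3, ... growing geometrically by `factor` once the
# rounded geometric sequence outpaces unit steps.
size_bins <- function(n_max, factor = 1.5) {
  b <- 1
  while (b[length(b)] <= n_max) {
    nxt <- max(b[length(b)] + 1, round(b[length(b)] * factor))
    b <- c(b, nxt)
  }
  b
}

#' Landau free-energy landscape from a monomer-occupancy distribution
#'
#' Computes \eqn{\Delta G_n = -k_B T \ln(p_n / (n\, p_1))}, the free energy
#' of an n-mer relative to free monomers, from binned occupancies. Occupancy
#' per integer size is obtained by dividing each bin's probability by its
#' width, so logarithmic binning does not distort the landscape (for width-1
#' bins this reduces exactly to the formula above). The reference bin has
#' \eqn{\Delta G = 0} exactly. Bins with zero probability or too few
#' observations are flagged censored: within experimental resolution the
#' free energy there effectively diverges.
#'
#' @param occupancy An [monomer_occupancy()] result.
#' @param monomer_bin Index of the reference (monomer) bin; by default the
#'   smallest populated size class (true monomers may be below detection, in
#'   which case the reference is the smallest detectable class, e.g. one
#'   labelled molecule).
#' @return A `free_energy_landscape` tibble: `n`, `dG_kT`, `n_obs`,
#'   `censored` (plus `ci_low`/`ci_high` when produced by
#'   [bootstrap_landscape()]).
#' @examples
#' occ <- monomer_occupancy(rep(c(1, 2, 4), c(50, 20, 10)))
#' free_energy(occ)
#' @export
free_energy <- function(occupancy, monomer_bin = NULL) {
  stopifnot(inherits(occupancy, "occupancy") || is.data.frame(occupancy))
  p <- occupancy$p
  if (is.null(monomer_bin)) monomer_bin <- which(p > 0)[1]
  if (is.na(monomer_bin) || p[monomer_bin] <= 0) {
    stop("no monomer reference: p = 0 at the reference bin", call. = FALSE)
  }
  dens <- p / occupancy$width
  ref <- dens[monomer_bin] / occupancy$n[monomer_bin]
  dg <- -log(dens / (occupancy$n * ref))
  dg[occupancy$n_obs == 0L] <- NA_real_
  out <- tibble::tibble(
    n = occupancy$n,
    dG_kT = dg,
    n_obs = occupancy$n_obs,
    censored = occupancy$censored | occupancy$n_obs == 0L
  )
  structure(out, monomer_bin = monomer_bin,
            class = c("free_energy_landscape", "tbl_df", "tbl", "data.frame"))
}

#' Bootstrap confidence bands for the free-energy landscape
#'
#' Resamples whole tracks with replacement (respecting within-track
#' autocorrelation), recomputes the occupancy-derived free energy for each
#' replicate, and reports percentile confidence intervals; the centre line is
#' the mean over bootstrap replicates.
#'
#' @param ensemble Data frame with columns `n` (cluster size, total
#'   molecules) and `track` (resampling unit; use cell+track identifiers).
#' @param bins,bin_factor,min_count Passed to [monomer_occupancy()] (the bin
#'   set is computed once from the full ensemble and held fixed).
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param level Confidence level (default 0.99).
#' @param monomer_bin Reference bin index.
#' @return A `free_energy_landscape` tibble with `dG_kT` (bootstrap mean),
#'   `ci_low`, `ci_high`, `dG_point` (plug-in estimate), `n_obs`, `censored`.
#' @export
bootstrap_landscape <- function(ensemble, bins = NULL, bin_factor = 1.5,
                                min_count = 5, n_boot = 10000, level = 0.99,
                                monomer_bin = NULL) {
  stopifnot(is.data.frame(ensemble), all(c("n", "track") %in% names(ensemble)))
  tracks <- unique(ensemble$track)
  if (length(tracks) < 2L) stop("need at least 2 tracks to bootstrap", call. = FALSE)

  occ <- monomer_occupancy(ensemble$n, bins = bins, bin_factor = bin_factor,
                           min_count = min_count)
  if (is.null(monomer_bin)) monomer_bin <- which(occ$p > 0)[1]
  point <- free_energy(occ, monomer_bin)
  breaks <- attr(occ, "breaks")
  nb <- nrow(occ)

  # per-track molecule mass per bin
  bin <- pmin(findInterval(ensemble$n, breaks), nb)
  tr <- match(ensemble$track, tracks)
  M <- matrix(0, length(tracks), nb)
  for (k in seq_along(bin)) M[tr[k], bin[k]] <- M[tr[k], bin[k]] + ensemble$n[k]
  Cnt <- matrix(0L, length(tracks), nb)
  for (k in seq_along(bin)) Cnt[tr[k], bin[k]] <- Cnt[tr[k], bin[k]] + 1L

  # bootstrap: multinomial track weights
  W <- stats::rmultinom(n_boot, size = length(tracks),
                        prob = rep(1, length(tracks)))
  P <- t(W) %*% M                       # n_boot x nb molecule mass
  P <- P / rowSums(P)
  dens <- sweep(P, 2, occ$width, "/")
  ref <- dens[, monomer_bin] / occ$n[monomer_bin]
  dG <- -log(sweep(sweep(dens, 2, occ$n, "/"), 1, ref, "/"))
  dG[!is.finite(dG)] <- NA

  alpha <- (1 - level) / 2
  ci <- apply(dG, 2, stats::quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  out <- tibble::tibble(
    n = occ$n,
    dG_kT = colMeans(dG, na.rm = TRUE),
    ci_low = ci[1, ], ci_high = ci[2, ],
    dG_point = point$dG_kT,
    n_obs = occ$n_obs,
    censored = point$censored
  )
  out$dG_kT[out$n_obs == 0L] <- NA_real_
  structure(out, monomer_bin = monomer_bin, n_boot = n_boot, level = level,
            class = c("free_energy_landscape", "tbl_df", "tbl", "data.frame"))
}

#' Fit the initial scaling of a free-energy landscape
#'
#' Least-squares fit of \eqn{\ln \Delta G = \ln A + \beta \ln n} over the
#' initial rise of the landscape. When `fit_range` is not given, the rise is
#' delimited automatically: an initial slope estimate from the first four
#' usable bins is refined by locating the plateau onset as the first bin
#' where the local log-log slope drops below half the initial slope.
#'
#' Because the occupancy estimator pins \eqn{\Delta G} to zero at the
#' monomer reference, a landscape whose absolute form is \eqn{A n^\beta}
#' appears as \eqn{A(n^\beta - 1)}, which is not a pure power law at small
#' sizes. `offset = "monomer"` therefore fits
#' \eqn{\Delta G = A(n^\beta - 1)} (nonlinear least squares), `"none"` fits
#' the pure power law in log-log space, and the default `"auto"` fits both
#' and keeps the one with the smaller residual sum of squares.
#'
#' @param landscape A `free_energy_landscape`.
#' @param fit_range Optional length-2 numeric: sizes (inclusive) to fit over.
#' @param offset Reference-offset handling: `"auto"`, `"none"`, `"monomer"`.
#' @return An object of class `scaling_fit`: list with `beta`, `amplitude`,
#'   `plateau_onset`, `n_bins`, `r_squared` and the fitted subset.
#' @examples
#' ls <- tibble::tibble(n = 2:50, dG_kT = 2 * (2:50)^(2 / 3),
#'                      n_obs = 100L, censored = FALSE)
#' class(ls) <- c("free_energy_landscape", class(ls))
#' fit_initial_scaling(ls)$beta
#' @export
fit_initial_scaling <- function(landscape, fit_range = NULL,
                                offset = c("auto", "none", "monomer")) {
  offset <- match.arg(offset)
  stopifnot(is.data.frame(landscape), all(c("n", "dG_kT") %in% names(landscape)))
  ok <- is.finite(landscape$dG_kT) & landscape$dG_kT > 0 &
    (!("censored" %in% names(landscape)) | !landscape$censored)
  d <- landscape[ok, ]
  d <- d[order(d$n), ]

  plateau_onset <- NA_real_
  if (is.null(fit_range)) {
    if (nrow(d) < 4L) stop("need at least 4 positive, uncensored bins", call. = FALSE)
    ln <- log(d$n); lg <- log(d$dG_kT)
    beta0 <- stats::coef(stats::lm(lg[1:4] ~ ln[1:4]))[2]
    local <- diff(lg) / diff(ln)
    drop_idx <- which(local < beta0 / 2)
    cut <- if (length(drop_idx) > 0L) max(4L, drop_idx[1]) else nrow(d)
    plateau_onset <- if (length(drop_idx) > 0L) d$n[drop_idx[1] + 1L] else NA_real_
    d <- d[seq_len(cut), ]
  } else {
    d <- d[d$n >= fit_range[1] & d$n <= fit_range[2], ]
    if (nrow(d) < 4L) stop("need at least 4 positive, uncensored bins in fit_range", call. = FALSE)
  }

  fit <- stats::lm(log(dG_kT) ~ log(n), data = d)
  co <- stats::coef(fit)
  beta <- unname(co[2]); amp <- exp(unname(co[1]))
  rss_pow <- sum((amp * d$n^beta - d$dG_kT)^2)
  model <- "power"

  if (offset != "none") {
    nfit <- tryCatch(
      stats::nls(dG_kT ~ A * (n^b - 1), data = d,
                 start = list(A = amp, b = beta),
                 control = stats::nls.control(warnOnly = TRUE)),
      error = function(e) NULL)
    if (!is.null(nfit)) {
      cn <- stats::coef(nfit)
      rss_off <- sum(stats::resid(nfit)^2)
      if (offset == "monomer" || rss_off < rss_pow) {
        beta <- unname(cn["b"]); amp <- unname(cn["A"])
        rss_pow <- rss_off
        model <- "power_monomer_offset"
        fit <- nfit
      }
    }
  }

  tss <- sum((d$dG_kT - mean(d$dG_kT))^2)
  structure(
    list(beta = beta, amplitude = amp, model = model,
         plateau_onset = plateau_onset, n_bins = nrow(d),
         r_squared = if (tss > 0) 1 - rss_pow / tss else NA_real_,
         data = d, fit = fit),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> dG ~ %.3g * n^%.3f over %d bins (R^2 = %.3f)\n",
              x$amplitude, x$beta, x$n_bins, x$r_squared))
  if (is.finite(x$plateau_onset)) cat("  plateau onset near n =", signif(x$plateau_onset, 3), "\n")
  invisible(x)
}

#' Nucleation lag times across cells
#'
#' The lag time of a cell is the delay from the start of its movie to its
#' nucleation frame. Cells without a detected nucleation are censored (they
#' contribute to `n_censored` but not to the dispersion). A broad lag-time
#' distribution (large coefficient of variation) is the hallmark of a
#' stochastic nucleation-and-growth mechanism.
#'
#' @param nucleation Tibble with `cell_id`, `nucleation_frame` (NA when
#'   censored), and optionally `frame_interval` (s; default 10).
#' @param frame_interval Seconds per frame if not a column.
#' @return An object of class `lag_summary`: tibble of per-cell lags with
#'   attributes `cv`, `mean_lag_s`, `n_censored`.
#' @export
lag_times <- function(nucleation, frame_interval = 10) {
  stopifnot(is.data.frame(nucleation),
            all(c("cell_id", "nucleation_frame") %in% names(nucleation)))
  fi <- if ("frame_interval" %in% names(nucleation)) nucleation$frame_interval else frame_interval
  out <- tibble::tibble(
    cell_id = nucleation$cell_id,
    lag_s = (nucleation$nucleation_frame - 1) * fi,
    censored = is.na(nucleation$nucleation_frame)
  )
  obs <- out$lag_s[!out$censored]
  cv <- if (length(obs) >= 2L && mean(obs) > 0) stats::sd(obs) / mean(obs) else NA_real_
  structure(out, cv = cv,
            mean_lag_s = if (length(obs)) mean(obs) else NA_real_,
            n_censored = sum(out$censored),
            class = c("lag_summary", "tbl_df", "tbl", "data.frame"))
}
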