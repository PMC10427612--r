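#' Sample cluster sizes directly from a Boltzmann distribution
#'
#' Draws cluster sizes with probability proportional to
#' \eqn{\exp(-\Delta G_n / k_B T)} over `1..size_max` by inverse-CDF sampling,
#' with no dynamics involved. This is the equilibrium cluster-number
#' distribution implied by a landscape; it is used to seed the kinetic
#' simulator and is convenient as a dynamics-free sampling route when testing
#' landscape estimators.
#'
#' @param landscape A [free_energy_landscape()].
#' @param n Number of clusters to draw.
#' @param size_max Largest size considered (truncated at any hard wall).
#' @return Integer vector of cluster sizes.
#' @export
sample_boltzmann <- function(landscape, n, size_max) {
  size_max <- min(size_max, landscape$size_limit)
  g <- landscape_table(landscape, size_max)
  w <- exp(-(g - min(g[is.finite(g)])))
  w[!is.finite(w)] <- 0
  sample.int(size_max, n, replace = TRUE, prob = w)
}

#' Simulate a single birth--death cluster-size chain
#'
#' Runs the continuous-time birth--death chain used by the cluster simulator
#' for a fixed number of jump events and returns the visited sizes together
#' with their exponential holding times. Time-weighted occupancies of this
#' chain converge to the Boltzmann distribution of the landscape, which makes
#' this function the natural check of detailed balance.
#'
#' @inheritParams sample_boltzmann
#' @param k_plus Attachment rate (s^-1).
#' @param n0 Initial size.
#' @param n_events Number of jump events to simulate.
#' @param size_max Largest size tabulated.
#' @param seed Optional integer seed.
#' @return A tibble with columns `size` (state before each jump) and
#'   `holding_s` (time spent there).
#' @export
simulate_birth_death_chain <- function(landscape, k_plus = 1, n0 = 1L,
                                       n_events = 1e4, size_max = 100L,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  size_max <- min(size_max, landscape$size_limit)
  dG <- landscape_table(landscape, size_max)
  up <- k_plus * c(is.finite(dG[-1]), FALSE)     # rate n -> n+1
  down <- k_plus * exp(dG - c(0, dG[-size_max])) # rate n -> n-1
  down[1] <- 0
  states <- integer(n_events)
  hold <- numeric(n_events)
  n <- as.integer(n0)
  u_jump <- stats::runif(n_events)
  for (i in seq_len(n_events)) {
    tot <- up[n] + down[n]
    if (tot <= 0) {
      states[i:n_events] <- n
      hold[i:n_events] <- Inf
      break
    }
    states[i] <- n
    hold[i] <- stats::rexp(1L, tot)
    n <- if (u_jump[i] * tot < up[n]) n + 1L else n - 1L
  }
  tibble::tibble(size = states, holding_s = hold)
}

#' Simulate diffusing clusters with birth--death size dynamics
#'
#' Generates the ground-truth side of a synthetic live-cell movie: a set of
#' clusters whose sizes follow a continuous-time birth--death chain on the
#' configured free-energy landscape (Gillespie-sampled between frames, only
#' frame-sampled sizes are emitted), whose centroids diffuse inside a
#' circular nuclear region, and whose labelled-molecule counts are thinned
#' at the configured labelling fraction. Optionally, clusters whose centres
#' approach within `contact_radius` coalesce, summing their sizes -- the
#' growth mechanism by which large condensates assemble.
#'
#' @param config A [sim_config()].
#' @return An object of class `cluster_sim`: list with `config`, `truth`
#'   (tibble: `frame`, `cluster_id`, `n_true`, `n_gfp_true`, `x_um`, `y_um`),
#'   `merges` (tibble: `frame`, `from_id`, `into_id`) and `nucleation`
#'   (one-row tibble with the ground-truth condensate id, critical size and
#'   nucleation frame/time, `NA` when no condensate formed).
#' @examples
#' sim <- simulate_cluster_dynamics(sim_config(n_frames = 5, n_clusters_init = 3, seed = 2))
#' head(sim$truth)
#' @export
simulate_cluster_dynamics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ls <- config$landscape

  # metastable initial ensemble: Boltzmann-distributed sizes, truncated at
  # any hard wall and at n_init_max (pre-nucleation cells carry clusters over
  # a broad size range but none beyond the critical scale)
  nc <- config$n_clusters_init
  sizes <- sample_boltzmann(ls, nc, size_max = config$n_init_max)
  n_gfp <- stats::rbinom(nc, sizes, config$label_fraction)

  n_tab <- as.integer(min(ls$size_limit, 8192L))
  dG <- landscape_table(ls, n_tab)

  field_um <- config$field_size * config$pixel_size
  centre <- field_um / 2
  nuc_r <- 0.42 * min(field_um)
  th <- stats::runif(nc, 0, 2 * pi)
  rr <- nuc_r * sqrt(stats::runif(nc))
  x <- centre[1] + rr * cos(th)
  y <- centre[2] + rr * sin(th)
  if (!config$coalescence) {
    rad0 <- sqrt(sizes * config$label_fraction / config$gfp_density_rho / pi)
    pos <- push_apart(x, y, rad0, config$contact_radius)
    x <- pos$x; y <- pos$y
  }

  step_sd <- sqrt(2 * config$diffusion_D * config$frame_interval^config$diffusion_alpha)
  alive <- rep(TRUE, nc)
  pool_used <- sum(sizes)

  out <- vector("list", config$n_frames)
  merges <- list()

  record <- function(frame) {
    tibble::tibble(frame = frame, cluster_id = which(alive),
                   n_true = sizes[alive], n_gfp_true = n_gfp[alive],
                   x_um = x[alive], y_um = y[alive])
  }
  out[[1L]] <- record(1L)

  for (f in seq_len(config$n_frames - 1L)) {
    for (i in which(alive)) {
      n <- sizes[i]; g <- n_gfp[i]
      t <- 0
      repeat {
        pool_ok <- pool_used < config$monomer_pool
        a <- if (pool_ok && n < n_tab && is.finite(dG[n + 1L])) config$k_plus else 0
        b <- if (n > 1L) config$k_plus * exp(dG[n] - dG[n - 1L]) else 0
        tot <- a + b
        if (tot <= 0) break
        t <- t + stats::rexp(1L, tot)
        if (t > config$frame_interval) break
        if (stats::runif(1L) * tot < a) {
          n <- n + 1L
          pool_used <- pool_used + 1
          if (stats::runif(1L) < config$label_fraction) g <- g + 1L
        } else {
          n <- n - 1L
          pool_used <- pool_used - 1
          if (stats::runif(1L) < g / (n + 1L)) g <- g - 1L
        }
      }
      sizes[i] <- n; n_gfp[i] <- g
    }

    # centroid diffusion with radial reflection at the nuclear boundary
    idx <- which(alive)
    x[idx] <- x[idx] + stats::rnorm(length(idx), 0, step_sd)
    y[idx] <- y[idx] + stats::rnorm(length(idx), 0, step_sd)
    dx <- x[idx] - centre[1]; dy <- y[idx] - centre[2]
    r <- sqrt(dx^2 + dy^2)
    over <- r > nuc_r
    if (any(over)) {
      scl <- (2 * nuc_r - r[over]) / r[over]
      scl <- pmax(scl, 0.05)
      x[idx[over]] <- centre[1] + dx[over] * scl
      y[idx[over]] <- centre[2] + dy[over] * scl
    }

    if (!config$coalescence) {
      # steric exclusion: distinct dense-phase droplets cannot interpenetrate
      # (in reality touching droplets would fuse; with coalescence disabled
      # they are kept apart instead), so rendered footprints never overlap
      idx <- which(alive)
      rad <- sqrt(sizes[idx] * config$label_fraction /
                    config$gfp_density_rho / pi)
      pos <- push_apart(x[idx], y[idx], rad, config$contact_radius)
      x[idx] <- pos$x; y[idx] <- pos$y
    }

    if (config$coalescence) {
      repeat {
        idx <- which(alive)
        if (length(idx) < 2L) break
        d <- as.matrix(stats::dist(cbind(x[idx], y[idx])))
        rad <- sqrt(sizes[idx] * config$label_fraction /
                      config$gfp_density_rho / pi)
        d <- d - outer(rad, rad, "+") # surface-to-surface separation
        d[upper.tri(d, diag = TRUE)] <- Inf
        hit <- which(d < config$contact_radius, arr.ind = TRUE)
        if (nrow(hit) == 0L) break
        pair <- idx[hit[1L, ]]
        big <- pair[which.max(sizes[pair])]
        small <- setdiff(pair, big)[1L]
        w <- sizes[c(big, small)]
        x[big] <- sum(x[c(big, small)] * w) / sum(w)
        y[big] <- sum(y[c(big, small)] * w) / sum(w)
        sizes[big] <- sizes[big] + sizes[small]
        n_gfp[big] <- n_gfp[big] + n_gfp[small]
        alive[small] <- FALSE
        merges[[length(merges) + 1L]] <-
          tibble::tibble(frame = f + 1L, from_id = small, into_id = big)
      }
    }
    out[[f + 1L]] <- record(f + 1L)
  }

  res <- structure(
    list(config = config,
         truth = dplyr::bind_rows(out),
         merges = if (length(merges)) dplyr::bind_rows(merges) else
           tibble::tibble(frame = integer(), from_id = integer(), into_id = integer())),
    class = "cluster_sim"
  )

  # Ground-truth nucleation from the true sizes: the condensate is the
  # cluster with the largest final size, declared only when clearly dominant
  # (final size at least 1.5x the largest size any other cluster reached);
  # the critical size is the maximum over all other clusters, and the
  # nucleation frame is the first frame from which the condensate stays
  # above it.
  truth <- res$truth
  finals <- truth[truth$frame == max(truth$frame), ]
  cond_id <- NA_integer_; crit_n <- NA_real_; nuc <- NA_integer_
  if (nrow(finals) > 0L) {
    cand <- finals$cluster_id[which.max(finals$n_true)]
    others <- truth[truth$cluster_id != cand, ]
    if (nrow(others) > 0L) {
      crit_n <- max(others$n_true)
      if (finals$n_true[finals$cluster_id == cand] >= 1.5 * crit_n) {
        cond_id <- as.integer(cand)
        ct <- truth[truth$cluster_id == cand, ]
        ct <- ct[order(ct$frame), ]
        below <- which(ct$n_true <= crit_n)
        first_idx <- if (length(below) == 0L) 1L else max(below) + 1L
        if (first_idx <= nrow(ct)) nuc <- as.integer(ct$frame[first_idx])
      }
    }
  }
  res$nucleation <- tibble::tibble(
    condensate_id = cond_id,
    critical_n = crit_n,
    critical_area_um2 = crit_n * config$label_fraction / config$gfp_density_rho,
    nucleation_frame = nuc,
    nucleation_time_s = (nuc - 1) * config$frame_interval
  )
  res
}

#' @export
print.cluster_sim <- function(x, ...) {
  cat("<cluster_sim>", x$config$n_clusters_init, "clusters,",
      x$config$n_frames, "frames,", nrow(x$merges), "merge events\n")
  cat("  true size range:", paste(range(x$truth$n_true), collapse = " - "), "molecules\n")
  invisible(x)
}

# Pairwise relaxation: push overlapping discs (radii rad, plus a contact
# margin) apart along their line of centres until no pair overlaps or the
# sweep budget is exhausted.
push_apart <- function(x, y, rad, contact, max_sweeps = 5L) {
  m <- length(x)
  if (m >= 2L) {
    for (sweep in seq_len(max_sweeps)) {
      moved <- FALSE
      for (a in 2:m) for (b in seq_len(a - 1L)) {
        dx <- x[a] - x[b]; dy <- y[a] - y[b]
        dd <- sqrt(dx^2 + dy^2)
        need <- rad[a] + rad[b] + contact
        if (dd < need) {
          if (dd < 1e-6) { dx <- 1; dy <- 0; dd <- 1 }
          push <- (need - dd) / 2 + 1e-3
          x[a] <- x[a] + push * dx / dd
          y[a] <- y[a] + push * dy / dd
          x[b] <- x[b] - push * dx / dd
          y[b] <- y[b] - push * dy / dd
          moved <- TRUE
        }
      }
      if (!moved) break
    }
  }
  list(x = x, y = y)
}

#' Convert simulated ground truth to a track table
#'
#' Re-expresses the true cluster trajectories in the same tabular schema the
#' segmentation/tracking stage produces, with areas derived from the true
#' labelled counts at the configured dense-phase density. Useful for testing
#' analysis stages in isolation from imaging noise.
#'
#' @param sim A `cluster_sim`.
#' @param cell_id Cell identifier attached to every row.
#' @return A track-table tibble (`cell_id`, `track_id`, `frame`, `time_s`,
#'   `x_um`, `y_um`, `area_um2`, `intensity`).
#' @export
truth_to_tracks <- function(sim, cell_id = 1L) {
  cfg <- sim$config
  dplyr::transmute(sim$truth,
    cell_id = cell_id,
    track_id = .data$cluster_id,
    frame = .data$frame,
    time_s = (.data$frame - 1) * cfg$frame_interval,
    x_um = .data$x_um, y_um = .data$y_um,
    area_um2 = .data$n_true * cfg$label_fraction / cfg$gfp_density_rho,
    intensity = .data$n_gfp_true * cfg$poisson_gain
  )
}
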