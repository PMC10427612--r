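#' Link per-frame regions into cluster tracks
#'
#' Frame-to-frame linking by optimal bipartite assignment on squared centroid
#' displacement (Jonker--Volgenant shortest augmenting paths), with links
#' beyond `max_disp_um` rejected, track memory across short gaps, and merge
#' detection: when a track loses its region but ends within `max_disp_um` of
#' a region claimed by another track, a merge event is recorded and the
#' larger antecedent keeps its identity.
#'
#' @param regions Tibble of regions with columns `frame`, `x_um`, `y_um`,
#'   `area_um2`, `intensity` (as produced by [segment_movie()]).
#' @param max_disp_um Maximum linking displacement per frame step (um);
#'   should comfortably exceed the typical per-frame diffusion step
#'   (`sqrt(4 D dt)`).
#' @param memory_frames Number of consecutive missed frames a track survives.
#' @param frame_interval Seconds per frame, used to fill `time_s`.
#' @return A track-table tibble (`track_id`, `frame`, `time_s`, `x_um`,
#'   `y_um`, `area_um2`, `intensity`, `n_px`, `gap`) sorted by track and
#'   frame, with a `merges` attribute (tibble `frame`, `from_id`, `into_id`).
#' @examples
#' regs <- tibble::tibble(frame = rep(1:3, each = 1), x_um = c(1, 1.1, 1.2),
#'                        y_um = 1, area_um2 = 0.1, intensity = 10, n_px = 4L)
#' link_tracks(regs, max_disp_um = 0.5)
#' @export
link_tracks <- function(regions, max_disp_um = 2, memory_frames = 2,
                        frame_interval = 10) {
  stopifnot(all(c("frame", "x_um", "y_um", "area_um2", "intensity") %in% names(regions)))
  if (!"n_px" %in% names(regions)) regions$n_px <- NA_integer_
  if (nrow(regions) == 0L) {
    out <- tibble::tibble(track_id = integer(), frame = integer(), time_s = numeric(),
                          x_um = numeric(), y_um = numeric(), area_um2 = numeric(),
                          intensity = numeric(), n_px = integer(), gap = logical())
    attr(out, "merges") <- tibble::tibble(frame = integer(), from_id = integer(),
                                          into_id = integer())
    return(out)
  }
  regions <- dplyr::arrange(regions, .data$frame)
  # iterate every frame in range: empty frames still age track memory
  frames <- seq(min(regions$frame), max(regions$frame))
  by_frame <- split(regions, regions$frame)

  next_id <- 0L
  # active track state
  act <- list() # each: id, x, y, area, miss
  rows <- list()
  merges <- list()

  add_row <- function(id, frame, reg_row, gap = FALSE) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      track_id = id, frame = frame,
      x_um = reg_row$x_um, y_um = reg_row$y_um,
      area_um2 = reg_row$area_um2, intensity = reg_row$intensity,
      n_px = reg_row$n_px, gap = gap)
  }

  for (f in frames) {
    regs <- by_frame[[as.character(f)]]
    if (is.null(regs)) regs <- regions[0, ]
    nr <- nrow(regs)
    nt <- length(act)
    assigned_reg <- rep(NA_integer_, nr) # track index per region
    if (nt > 0L && nr > 0L) {
      tx <- vapply(act, `[[`, numeric(1), "x")
      ty <- vapply(act, `[[`, numeric(1), "y")
      d2 <- outer(tx, regs$x_um, function(a, b) (a - b)^2) +
            outer(ty, regs$y_um, function(a, b) (a - b)^2)
      sol <- lap_link(d2, max_cost = max_disp_um^2)
      for (t in seq_len(nt)) {
        if (!is.na(sol[t])) assigned_reg[sol[t]] <- t
      }
    }

    new_act <- list()
    # tracks that found a region
    matched_tracks <- stats::na.omit(assigned_reg)
    for (r in seq_len(nr)) {
      t <- assigned_reg[r]
      if (!is.na(t)) {
        st <- act[[t]]
        add_row(st$id, f, regs[r, ], gap = st$miss > 0L)
        new_act[[length(new_act) + 1L]] <-
          list(id = st$id, x = regs$x_um[r], y = regs$y_um[r],
               area = regs$area_um2[r], miss = 0L)
      }
    }
    # unmatched tracks: merge detection, then memory
    for (t in setdiff(seq_len(nt), matched_tracks)) {
      st <- act[[t]]
      merged <- FALSE
      if (nr > 0L) {
        d <- sqrt((st$x - regs$x_um)^2 + (st$y - regs$y_um)^2)
        cand <- which(d <= max_disp_um & !is.na(assigned_reg))
        if (length(cand) > 0L) {
          r <- cand[which.min(d[cand])]
          other <- act[[assigned_reg[r]]]
          # larger antecedent keeps its id
          if (st$area > other$area) {
            # the larger antecedent keeps its id: the continuing state (and
            # the row just added for `other` at this frame) take st's id
            for (k in seq_along(new_act)) {
              if (new_act[[k]]$id == other$id) { new_act[[k]]$id <- st$id; break }
            }
            for (k in rev(seq_along(rows))) {
              if (rows[[k]]$frame == f && rows[[k]]$track_id == other$id) {
                rows[[k]]$track_id <- st$id
                break
              }
            }
            merges[[length(merges) + 1L]] <-
              tibble::tibble(frame = f, from_id = other$id, into_id = st$id)
          } else {
            merges[[length(merges) + 1L]] <-
              tibble::tibble(frame = f, from_id = st$id, into_id = other$id)
          }
          merged <- TRUE
        }
      }
      if (!merged && st$miss < memory_frames) {
        st$miss <- st$miss + 1L
        new_act[[length(new_act) + 1L]] <- st
      }
    }
    # unmatched regions start new tracks
    for (r in which(is.na(assigned_reg))) {
      next_id <- next_id + 1L
      add_row(next_id, f, regs[r, ])
      new_act[[length(new_act) + 1L]] <-
        list(id = next_id, x = regs$x_um[r], y = regs$y_um[r],
             area = regs$area_um2[r], miss = 0L)
    }
    act <- new_act
  }

  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, time_s = (.data$frame - 1) * frame_interval,
                       .after = "frame")
  out <- dplyr::arrange(out, .data$track_id, .data$frame)
  attr(out, "merges") <- if (length(merges)) dplyr::bind_rows(merges) else
    tibble::tibble(frame = integer(), from_id = integer(), into_id = integer())
  out
}

# Gated linear assignment: rows = tracks, cols = regions. Entries of d2 above
# max_cost are forbidden. Returns, per row, the assigned column or NA.
# Solved optimally on an augmented square matrix where every row/column can
# fall back to a "no match" slot at cost max_cost.
lap_link <- function(d2, max_cost) {
  nt <- nrow(d2); nr <- ncol(d2)
  BIG <- (max(c(d2[is.finite(d2)], max_cost)) + 1) * 1e6
  n <- nt + nr
  C <- matrix(BIG, n, n)
  tl <- d2
  tl[tl > max_cost] <- BIG
  C[seq_len(nt), seq_len(nr)] <- tl
  for (i in seq_len(nt)) C[i, nr + i] <- max_cost
  for (j in seq_len(nr)) C[nt + j, j] <- max_cost
  C[(nt + 1):n, (nr + 1):n] <- 0
  sol <- solve_lap(C)
  assign <- sol[seq_len(nt)]
  assign[assign > nr] <- NA_integer_
  # forbid gated links that survived only because everything else was BIG
  for (i in seq_len(nt)) {
    if (!is.na(assign[i]) && d2[i, assign[i]] > max_cost) assign[i] <- NA_integer_
  }
  assign
}

# Exact linear assignment problem solver (square cost matrix), Hungarian
# algorithm with potentials and shortest augmenting paths, O(n^3).
# Returns the column assigned to each row.
solve_lap <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- Inf
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j + 1]: row matched to column j (0 = virtual col)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF; j1 <- 0L
      free <- which(!used[-1])   # candidate columns 1..n
      if (length(free) > 0L) {
        cur <- cost[i0, free] - u[i0 + 1L] - v[free + 1L]
        upd <- cur < minv[free + 1L]
        minv[free[upd] + 1L] <- cur[upd]
        way[free[upd] + 1L] <- j0
        k <- which.min(minv[free + 1L])
        delta <- minv[free[k] + 1L]
        j1 <- free[k]
      }
      if (!is.finite(delta)) stop("assignment infeasible", call. = FALSE)
      sel <- used
      u[p[which(sel)] + 1L] <- u[p[which(sel)] + 1L] + delta
      v[which(sel)] <- v[which(sel)] - delta
      minv[!sel] <- minv[!sel] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  rowsol <- integer(n)
  rowsol[p[-1]] <- seq_len(n)
  rowsol
}
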