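test_that("the assignment solver matches brute-force enumeration", {
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    C <- matrix(stats::runif(n * n, 0, 10), n)
    sol <- precondensate:::solve_lap(C)
    expect_equal(sort(sol), seq_len(n)) # a permutation
    expect_equal(sum(C[cbind(seq_len(n), sol)]), brute_lap_cost(C),
                 tolerance = 1e-10)
  }
})

test_that("a stationary spot over 5 frames yields one track of length 5", {
  regs <- tibble::tibble(frame = 1:5, x_um = 2, y_um = 3, area_um2 = 0.5,
                         intensity = 100, n_px = 20L)
  trk <- link_tracks(regs, max_disp_um = 1)
  expect_equal(length(unique(trk$track_id)), 1L)
  expect_equal(nrow(trk), 5L)
  expect_equal(trk$frame, 1:5)
})

test_that("two spots far beyond max_disp stay two tracks with no swaps", {
  regs <- dplyr::bind_rows(
    tibble::tibble(frame = 1:6, x_um = 2 + 0.05 * (1:6), y_um = 2,
                   area_um2 = 0.5, intensity = 100, n_px = 20L),
    tibble::tibble(frame = 1:6, x_um = 20, y_um = 20 + 0.05 * (1:6),
                   area_um2 = 0.3, intensity = 60, n_px = 12L)
  )
  trk <- link_tracks(regs, max_disp_um = 1)
  expect_equal(length(unique(trk$track_id)), 2L)
  by_track <- split(trk, trk$track_id)
  for (tt in by_track) {
    expect_true(all(tt$x_um < 10) || all(tt$x_um > 10)) # no identity swap
    expect_equal(nrow(tt), 6L)
  }
})

test_that("well-separated simulated clusters are tracked with full correspondence", {
  # 20 clusters on a grid, per-frame displacement far below the spacing
  set.seed(3)
  n_cl <- 20; n_fr <- 12
  gx <- rep(seq(2, 17, length.out = 5), 4)
  gy <- rep(seq(2, 14, length.out = 4), each = 5)
  regs <- purrr::map_dfr(seq_len(n_fr), function(f) {
    tibble::tibble(frame = f,
                   x_um = gx + cumsum(rep(0.08, n_cl)) * 0 + stats::rnorm(n_cl, 0, 0.15),
                   y_um = gy + stats::rnorm(n_cl, 0, 0.15),
                   area_um2 = rep(0.5, n_cl), intensity = 100,
                   n_px = 20L, true_id = seq_len(n_cl))
  })
  trk <- link_tracks(regs, max_disp_um = 1)
  # recover the correspondence via positions: every track must contain a
  # single true id across all frames
  trk$true_id <- regs$true_id[match(paste(trk$frame, trk$x_um), paste(regs$frame, regs$x_um))]
  per <- tapply(trk$true_id, trk$track_id, function(v) length(unique(v)))
  expect_equal(length(per), n_cl)
  expect_true(all(per == 1L))
  expect_true(all(tapply(trk$frame, trk$track_id, length) == n_fr))
})

test_that("tracks survive short gaps but close after the memory runs out", {
  regs <- tibble::tibble(frame = c(1, 2, 3, 6, 10), x_um = 2, y_um = 2,
                         area_um2 = 0.5, intensity = 100, n_px = 20L)
  trk <- link_tracks(regs, max_disp_um = 1, memory_frames = 2)
  # the 2-frame gap (4, 5) is bridged; the 3-frame gap (7-9) closes the track
  ids <- unique(trk$track_id)
  expect_equal(length(ids), 2L)
  expect_equal(trk$frame[trk$track_id == ids[1]], c(1, 2, 3, 6))
  expect_true(any(trk$gap))
})

test_that("merging regions record a merge event and keep the larger antecedent", {
  regs <- dplyr::bind_rows(
    tibble::tibble(frame = 1:3, x_um = 2, y_um = 2, area_um2 = 1.0,
                   intensity = 200, n_px = 40L),
    tibble::tibble(frame = 1:3, x_um = c(3.4, 2.9, 2.4), y_um = 2,
                   area_um2 = 0.3, intensity = 60, n_px = 12L),
    tibble::tibble(frame = 4, x_um = 2.05, y_um = 2, area_um2 = 1.3,
                   intensity = 260, n_px = 52L)
  )
  trk <- link_tracks(regs, max_disp_um = 1)
  merges <- attr(trk, "merges")
  expect_equal(nrow(merges), 1L)
  big_id <- trk$track_id[trk$frame == 1 & trk$area_um2 == 1.0]
  expect_equal(merges$into_id, big_id)
  expect_equal(trk$track_id[trk$frame == 4], big_id)
})

test_that("every region belongs to exactly one track", {
  sim <- small_movie_sim(seed = 6, n_frames = 8)
  regs <- segment_movie(render_movie(sim))
  trk <- link_tracks(regs, frame_interval = 10)
  expect_equal(nrow(trk), nrow(regs))
  expect_false(any(duplicated(trk[, c("frame", "x_um", "y_um")])))
})
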