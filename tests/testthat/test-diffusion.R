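test_that("MSD is zero for a stationary track and exact for ballistic motion", {
  still <- tibble::tibble(time_s = (0:19) * 10, x_um = 1, y_um = 2)
  m <- msd(still)
  expect_true(all(m$msd_um2 == 0))
  v <- 0.03
  ball <- tibble::tibble(time_s = (0:39) * 10, x_um = v * (0:39) * 10, y_um = 0)
  mb <- msd(ball)
  expect_equal(mb$msd_um2, v^2 * mb$lag_s^2, tolerance = 1e-12)
})

test_that("MSD averages over all ordered pairs and stops at a quarter length", {
  set.seed(1)
  tr <- tibble::tibble(time_s = (0:19) * 5, x_um = stats::rnorm(20),
                       y_um = stats::rnorm(20))
  m <- msd(tr)
  expect_equal(nrow(m), 5L) # floor(0.25 * 20)
  # oracle at lag 2
  dx <- tr$x_um[3:20] - tr$x_um[1:18]; dy <- tr$y_um[3:20] - tr$y_um[1:18]
  expect_equal(m$msd_um2[2], mean(dx^2 + dy^2), tolerance = 1e-14)
  expect_equal(m$n_pairs, 20 - 1:5)
  expect_error(msd(tr[1:6, ]), "too short")
})

test_that("exact diffusion-law inputs return the generating parameters", {
  curve <- tibble::tibble(lag = 1:10, lag_s = (1:10) * 1.0,
                          msd_um2 = 4 * 0.5 * (1:10))
  ff <- fit_diffusion(curve, "free")
  expect_equal(ff$D, 0.5, tolerance = 1e-12)
  fg <- fit_diffusion(curve, "generalized")
  expect_equal(fg$alpha, 1, tolerance = 1e-12)
  expect_equal(fg$D, 0.5, tolerance = 1e-12)
  expect_equal(fg$classification, "free")
  ball <- tibble::tibble(lag_s = (1:10) * 1.0, msd_um2 = (2 * (1:10))^2)
  fb <- fit_diffusion(ball, "generalized")
  expect_equal(fb$alpha, 2, tolerance = 1e-12)
  expect_equal(fb$classification, "directed")
  expect_error(fit_diffusion(curve[1:3, ], "free"), "at least 4")
})

test_that("free and generalised fits agree on exact Brownian input", {
  curve <- tibble::tibble(lag_s = (1:12) * 10, msd_um2 = 4 * 0.02 * (1:12) * 10)
  expect_equal(fit_diffusion(curve, "free")$D,
               fit_diffusion(curve, "generalized")$D, tolerance = 1e-10)
})

test_that("simulated tracks recover their generating parameters", {
  # zero diffusion: all positions identical
  tr0 <- simulate_track(D = 0, alpha = 1, dt = 10, n_steps = 30, seed = 1)
  expect_true(all(tr0$x_um == 0) && all(tr0$y_um == 0))
  # ballistic limit alpha = 2: MSD = v^2 t^2 with v = 2 sqrt(D)
  tr2 <- simulate_track(D = 0.04, alpha = 2, dt = 5, n_steps = 40, seed = 2)
  m2 <- msd(tr2)
  expect_equal(m2$msd_um2, 4 * 0.04 * m2$lag_s^2, tolerance = 1e-10)
  # Brownian D recovery within 20% (averaged over a few tracks)
  Ds <- vapply(1:16, function(s) {
    tr <- simulate_track(D = 0.1, alpha = 1, dt = 10, n_steps = 1000, seed = s)
    fit_diffusion(msd(tr), "free")$D
  }, numeric(1))
  expect_lt(abs(mean(Ds) - 0.1) / 0.1, 0.2)
  # subdiffusive exponent recovery within 0.1 on an ensemble
  as <- vapply(1:20, function(s) {
    tr <- simulate_track(D = 0.01, alpha = 0.6, dt = 10, n_steps = 300, seed = s)
    fit_diffusion(msd(tr), "generalized")$alpha
  }, numeric(1))
  expect_lt(abs(mean(as) - 0.6), 0.1)
  expect_true(mean(as < 1 - 0.2) > 0.8) # mostly classified subdiffusive
})

test_that("fractional increments reproduce the fBm covariance scaling", {
  # variance of x(t) grows as 2 D t^alpha
  al <- 1.5
  xs <- vapply(1:60, function(s) {
    tr <- simulate_track(D = 0.05, alpha = al, dt = 2, n_steps = 64, seed = 100 + s)
    tr$x_um[65]
  }, numeric(1))
  v_emp <- stats::var(xs)
  v_theo <- 2 * 0.05 * (64 * 2)^al
  expect_lt(abs(v_emp - v_theo) / v_theo, 0.55) # 60 samples: sd ~ sqrt(2/59)
})

test_that("per-track fitting excludes short tracks with a reason", {
  trks <- dplyr::bind_rows(
    dplyr::mutate(simulate_track(0.05, 1, 10, 60, seed = 3), track_id = 1L),
    dplyr::mutate(simulate_track(0.05, 1, 10, 5, seed = 4), track_id = 2L)
  )
  res <- fit_tracks_diffusion(trks, min_length = 10)
  expect_equal(res$track_id, 1L)
  exc <- attr(res, "excluded")
  expect_equal(exc$track_id, 2L)
  expect_match(exc$reason, "length")
})
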