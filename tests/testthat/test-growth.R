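test_that("the size gradient follows the printed formula", {
  expect_equal(size_gradient(c(5, 5, 5)), 0)
  expect_equal(size_gradient(c(1, 3, 2)), 1) # (2 + 1) / 3
  expect_true(is.na(size_gradient(7)))
})

test_that("the size gradient matches a naive loop oracle on random walks", {
  set.seed(8)
  for (r in 1:20) {
    a <- abs(cumsum(stats::rnorm(sample(5:60, 1))))
    oracle <- 0
    for (i in 2:length(a)) oracle <- oracle + abs(a[i] - a[i - 1])
    oracle <- oracle / length(a)
    expect_equal(size_gradient(a), oracle, tolerance = 1e-14)
  }
})

test_that("the size gradient is invariant under time reversal and scales with units", {
  set.seed(9)
  a <- abs(cumsum(stats::rnorm(30)))
  expect_equal(size_gradient(a), size_gradient(rev(a)))
  expect_equal(size_gradient(3.7 * a), 3.7 * size_gradient(a))
})

test_that("scaled copies of one trajectory have identical normalised gradients", {
  base <- c(1, 1.4, 1.2, 1.8, 1.5, 2.0)
  trk <- purrr::map_dfr(1:6, function(k) {
    tibble::tibble(track_id = k, frame = seq_along(base), area_um2 = k * base)
  })
  res <- normalized_gradient_distribution(trk, n_groups = 3)
  expect_lt(res$dispersion, 1e-12)
  expect_lt(max(res$per_track$norm_grad) - min(res$per_track$norm_grad), 1e-12)
})

test_that("coalescence growth gives flat normalised gradients; stepwise growth does not", {
  set.seed(10)
  # coalescence-like: area changes proportional to current area
  # (geometric random walk)
  coal <- purrr::map_dfr(1:100, function(k) {
    a0 <- stats::runif(1, 0.2, 5)
    tibble::tibble(track_id = k, frame = 1:31,
                   area_um2 = a0 * exp(cumsum(c(0, 0.15 * stats::rnorm(30)))))
  })
  rc <- normalized_gradient_distribution(coal)
  meds <- rc$per_group$med_norm_grad
  expect_lt(max(meds) / min(meds), 2)
  # stepwise (monomer attachment): absolute change independent of size
  step <- purrr::map_dfr(1:100, function(k) {
    a0 <- stats::runif(1, 0.2, 5)
    tibble::tibble(track_id = k, frame = 1:31,
                   area_um2 = abs(a0 + cumsum(c(0, 0.05 * stats::rnorm(30)))) + 0.01)
  })
  rs <- normalized_gradient_distribution(step)
  g <- rs$per_group
  # raw gradient roughly size-independent...
  expect_lt(max(g$med_raw_grad) / min(g$med_raw_grad), 2.5)
  # ...so the normalised gradient falls with size
  expect_lt(g$med_norm_grad[nrow(g)], 0.5 * g$med_norm_grad[1])
})

test_that("the small-cluster occupancy series flags Ostwald-like transfer", {
  # static ensemble: slope exactly zero
  static <- purrr::map_dfr(1:10, function(k) {
    tibble::tibble(track_id = k, frame = 1:10, n_total = 50 * k)
  })
  r0 <- ostwald_diagnostic(static, critical_n = 200, n_boot = 50)
  expect_equal(r0$slope, 0, tolerance = 1e-12)

  # Ostwald regime: mid-sized clusters shrink while the condensate grows;
  # occupancy below the critical size drains away (negative trend)
  ost <- dplyr::bind_rows(
    purrr::map_dfr(1:8, function(k) {
      tibble::tibble(track_id = k, frame = 1:20,
                     n_total = pmax(300 - 15 * (1:20) + 5 * k, 5))
    }),
    tibble::tibble(track_id = 99L, frame = 1:20, n_total = 2000 + 120 * (1:20))
  )
  ro <- ostwald_diagnostic(ost, critical_n = 500, n_boot = 100)
  expect_lt(ro$slope, 0)
  expect_lt(ro$ci_high, 0)

  # coalescence regime: small clusters are swallowed whole; the small-cluster
  # share declines monotonically with no transient increase
  coal <- dplyr::bind_rows(
    purrr::map_dfr(1:8, function(k) {
      last <- 2 + 2 * k
      tibble::tibble(track_id = k, frame = 1:last, n_total = 150)
    }),
    tibble::tibble(track_id = 99L, frame = 1:20,
                   n_total = 1500 + cumsum(c(0, rep(150, 19))))
  )
  rc <- ostwald_diagnostic(coal, critical_n = 500, n_boot = 100)
  expect_lte(max(rc$series$p_small), rc$series$p_small[1])
})
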