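test_that("per-cell critical areas average to the printed summary", {
  per_cell <- c(13, 17, 14, 12, 10, 19, 17, 13) # cell 9's 28 excluded as outlier
  expect_equal(mean(per_cell), 14.375, tolerance = 1e-12)
  expect_lt(abs(mean(per_cell) - 14), 3)        # consistent with 14 +/- 3
  expect_equal(stats::sd(per_cell), 3, tolerance = 0.2)
})

test_that("critical size is the largest non-condensate area and may be missing", {
  trk <- dplyr::bind_rows(
    tibble::tibble(track_id = 1L, frame = 1:5, area_um2 = c(5, 10, 16, 20, 30)),
    tibble::tibble(track_id = 2L, frame = 1:5, area_um2 = c(3, 6, 4, 5, 2)),
    tibble::tibble(track_id = 3L, frame = 1:5, area_um2 = c(8, 14, 9, 7, 6))
  )
  crit <- critical_size(trk, condensate_id = 1L)
  expect_equal(crit$critical_area_um2, 14)
  expect_equal(crit$critical_n, 14 * 29 / 0.2)
  # a cell with only the condensate has no defined critical size
  solo <- tibble::tibble(track_id = 1L, frame = 1:4, area_um2 = c(1, 2, 4, 8))
  crit2 <- critical_size(solo, condensate_id = 1L)
  expect_true(is.na(crit2$critical_area_um2))
  # exclusion flag drops motion-artefact tracks
  crit3 <- critical_size(trk, condensate_id = 1L, exclude_tracks = 3L)
  expect_equal(crit3$critical_area_um2, 6)
})

test_that("the nucleation crossing rule honours 'never falls below again'", {
  mk <- function(areas) tibble::tibble(track_id = 1L, frame = seq_along(areas),
                                       area_um2 = areas)
  sp1 <- split_pre_post(mk(c(5, 10, 16, 20, 30)), 14, condensate_id = 1L)
  expect_equal(attr(sp1, "nucleation_frame"), 3L)
  sp2 <- split_pre_post(mk(c(5, 16, 10, 20, 30)), 14, condensate_id = 1L)
  expect_equal(attr(sp2, "nucleation_frame"), 4L)
  expect_equal(sp2$phase, c("pre", "pre", "pre", "post", "post"))
  # no crossing: everything pre
  sp3 <- split_pre_post(mk(c(5, 6, 7, 8, 9)), 14, condensate_id = 1L)
  expect_true(is.na(attr(sp3, "nucleation_frame")))
  expect_true(all(sp3$phase == "pre"))
})

test_that("pipeline nucleation frames match ground truth when the condensate is unambiguous", {
  matched <- 0; agreeing <- 0
  for (s in c(1, 3, 4)) {
    cfg <- sim_config(coalescence = TRUE, n_frames = 150, n_clusters_init = 30,
                      n_init_max = 150, diffusion_D = 0.02, seed = s)
    sim <- simulate_cluster_dynamics(cfg)
    tn <- sim$nucleation$nucleation_frame
    if (is.na(tn)) next
    trk <- link_tracks(segment_movie(render_movie(sim)),
                       frame_interval = cfg$frame_interval)
    crit <- critical_size(trk)
    if (is.na(crit$condensate_id[1]) || !is.finite(crit$critical_area_um2[1])) next
    # same condensate identified? (critical sizes agree closely)
    if (abs(crit$critical_area_um2[1] - sim$nucleation$critical_area_um2) /
        sim$nucleation$critical_area_um2 > 0.25) next
    matched <- matched + 1
    nf <- attr(split_pre_post(trk, crit$critical_area_um2[1],
                              crit$condensate_id[1]), "nucleation_frame")
    if (!is.na(nf) && abs(nf - tn) <= 2) agreeing <- agreeing + 1
  }
  expect_gte(matched, 2)
  expect_equal(agreeing, matched)
})

test_that("monomer occupancy matches a brute-force per-molecule tally", {
  expect_equal(monomer_occupancy(c(1, 3))$p[c(1, 3)], c(1 / 4, 3 / 4))
  expect_equal(monomer_occupancy(rep(1, 10))$p[1], 1)
  set.seed(4)
  sizes <- sample(1:40, 1000, replace = TRUE, prob = 1 / (1:40))
  occ <- monomer_occupancy(sizes)
  breaks <- attr(occ, "breaks")
  # oracle: count each molecule individually into its cluster's bin
  molecules <- rep(sizes, times = sizes)
  bin <- pmin(findInterval(molecules, breaks), nrow(occ))
  oracle <- tabulate(bin, nrow(occ)) / length(molecules)
  expect_equal(occ$p, oracle, tolerance = 1e-12)
  expect_equal(sum(occ$p), 1)
  expect_error(monomer_occupancy(numeric(0)), "empty")
})

test_that("occupancy and free energy are invariant under duplicating the data", {
  set.seed(5)
  sizes <- sample(1:60, 400, replace = TRUE)
  o1 <- monomer_occupancy(sizes)
  o2 <- monomer_occupancy(c(sizes, sizes))
  expect_equal(o1$p, o2$p)
  expect_equal(free_energy(o1)$dG_kT, free_energy(o2)$dG_kT)
})

test_that("free energy is zero at the reference and flat for p_n ~ n p_1", {
  occ <- monomer_occupancy(rep(c(1, 2, 3), c(60, 30, 20)))
  fel <- free_energy(occ)
  expect_equal(fel$dG_kT[1], 0)
  # p_n proportional to n p_1 over unit bins -> flat landscape: equal cluster
  # counts per size give molecule mass proportional to n
  sizes <- rep(1:4, times = c(25, 25, 25, 25))
  fel2 <- free_energy(monomer_occupancy(sizes, bins = 1:5))
  expect_equal(fel2$dG_kT[1:4], rep(0, 4), tolerance = 1e-12)
  # an ensemble without any monomer reference errors
  occ3 <- monomer_occupancy(c(10, 12, 14), bins = c(1, 2, 20))
  expect_error(free_energy(occ3, monomer_bin = 1), "monomer reference")
})

test_that("Boltzmann-sampled ensembles recover the landscape within 0.2 kT", {
  c0 <- 0.5
  ls <- free_energy_landscape("custom", custom_fn = function(n) c0 * n^(2 / 3))
  set.seed(7)
  sizes <- sample_boltzmann(ls, 5e4, size_max = 400)
  occ <- monomer_occupancy(sizes)
  fel <- free_energy(occ)
  # enumeration oracle for the binned truth
  nmax <- 400
  p_clu <- exp(-(c0 * (1:nmax)^(2 / 3) - c0))
  mass <- p_clu * (1:nmax); mass <- mass / sum(mass)
  breaks <- attr(occ, "breaks")
  bin <- pmin(findInterval(1:nmax, breaks), nrow(occ))
  Pbin <- as.numeric(rowsum(mass, bin))
  dens <- Pbin / occ$width
  ref <- dens[1] / occ$n[1]
  dg_true <- -log(dens / (occ$n * ref))
  well <- !occ$censored & occ$n_obs >= 50
  expect_true(sum(well) >= 6)
  expect_lt(max(abs(fel$dG_kT[well] - dg_true[well])), 0.2)
})

test_that("bootstrap bands behave at the degenerate limits", {
  # zero-variance ensemble: identical tracks -> zero-width CI
  ens <- tibble::tibble(n = rep(4, 60), track = rep(1:12, each = 5))
  bl <- bootstrap_landscape(ens, n_boot = 200)
  pop <- which(bl$n_obs > 0)
  expect_equal(bl$ci_low[pop], bl$ci_high[pop])
  # n_boot = 1: band collapses onto the single replicate
  ens2 <- tibble::tibble(n = c(rep(1, 30), rep(3, 30)),
                         track = rep(1:12, each = 5))
  bl1 <- bootstrap_landscape(ens2, n_boot = 1)
  pop2 <- which(bl1$n_obs > 0)
  expect_equal(bl1$ci_low[pop2], bl1$ci_high[pop2])
  expect_equal(bl1$ci_low[pop2], bl1$dG_kT[pop2])
  expect_error(bootstrap_landscape(tibble::tibble(n = 1:5, track = 1)),
               "at least 2 tracks")
})

test_that("99% bootstrap bands cover the true landscape at the nominal rate", {
  # scaled-down coverage check; the full 200-replication study runs in the
  # acceptance suite
  c0 <- 0.5
  ls <- free_energy_landscape("custom", custom_fn = function(n) c0 * n^(2 / 3))
  nmax <- 400
  p_clu <- exp(-(c0 * (1:nmax)^(2 / 3) - c0))
  mass <- p_clu * (1:nmax); mass <- mass / sum(mass)
  set.seed(11)
  cover <- 0; total <- 0
  for (r in 1:40) {
    ens <- tibble::tibble(n = sample_boltzmann(ls, 1200, size_max = nmax),
                          track = rep(1:40, each = 30))
    bl <- bootstrap_landscape(ens, n_boot = 1000, level = 0.99)
    breaks <- attr(monomer_occupancy(ens$n), "breaks")
    bin <- pmin(findInterval(1:nmax, breaks), nrow(bl))
    Pbin <- rep(0, nrow(bl))
    s <- rowsum(mass, bin); Pbin[as.integer(rownames(s))] <- s
    occ <- monomer_occupancy(ens$n)
    dens <- Pbin / occ$width; ref <- dens[1] / occ$n[1]
    dg_true <- -log(dens / (occ$n * ref))
    ok <- !bl$censored & is.finite(bl$ci_low)
    cover <- cover + sum(bl$ci_low[ok] <= dg_true[ok] & dg_true[ok] <= bl$ci_high[ok])
    total <- total + sum(ok)
  }
  expect_gte(cover / total, 0.95)
})

test_that("initial-scaling fits recover exact and sampled exponents", {
  # exact surface scaling: beta = 2/3 to 1e-6
  ls1 <- structure(tibble::tibble(n = 2:50, dG_kT = 2 * (2:50)^(2 / 3),
                                  n_obs = 100L, censored = FALSE),
                   class = c("free_energy_landscape", "tbl_df", "tbl", "data.frame"))
  f1 <- fit_initial_scaling(ls1)
  expect_equal(f1$beta, 2 / 3, tolerance = 1e-6)
  expect_equal(f1$amplitude, 2, tolerance = 1e-6)
  # exact volume scaling: beta = 1
  ls2 <- structure(tibble::tibble(n = 2:50, dG_kT = 0.37 * (2:50),
                                  n_obs = 100L, censored = FALSE),
                   class = c("free_energy_landscape", "tbl_df", "tbl", "data.frame"))
  expect_equal(fit_initial_scaling(ls2)$beta, 1, tolerance = 1e-6)
  # kinetic-simulation route through the full estimator chain
  cfg <- sim_config(n_frames = 150, n_clusters_init = 30, n_init_max = 200,
                    seed = 3)
  sim <- simulate_cluster_dynamics(cfg)
  fel <- free_energy(monomer_occupancy(sim$truth$n_true))
  f3 <- fit_initial_scaling(fel, offset = "monomer")
  expect_lt(abs(f3$beta - 2 / 3), 0.1)
  # too few usable bins errors
  expect_error(fit_initial_scaling(ls1[1:3, ]), "at least 4")
})

test_that("lag times summarise nucleation delays with censoring", {
  same <- tibble::tibble(cell_id = 1:5, nucleation_frame = 21)
  lg <- lag_times(same, frame_interval = 10)
  expect_equal(attr(lg, "cv"), 0)
  expect_equal(attr(lg, "mean_lag_s"), 200)
  none <- tibble::tibble(cell_id = 1:4, nucleation_frame = NA_integer_)
  lg2 <- lag_times(none)
  expect_true(is.na(attr(lg2, "cv")))
  expect_equal(attr(lg2, "n_censored"), 4L)
  # stochastic nucleation is broadly distributed across cells
  nf <- vapply(1:8, function(s) {
    cfg <- sim_config(coalescence = TRUE, n_frames = 150, n_clusters_init = 30,
                      n_init_max = 150, diffusion_D = 0.02, seed = s)
    as.numeric(simulate_cluster_dynamics(cfg)$nucleation$nucleation_frame)
  }, numeric(1))
  lg3 <- lag_times(tibble::tibble(cell_id = 1:8, nucleation_frame = nf))
  expect_gte(sum(!lg3$censored), 3)
  expect_gt(attr(lg3, "cv"), 0.3)
})
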