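test_that("two-state chain reaches the Boltzmann occupancy ratio", {
  # analytic stationary distribution of a 2-state birth-death chain with
  # dG2 = 1 kT: p(2)/p(1) = exp(-1)
  ls2 <- free_energy_landscape("custom", custom_fn = function(n) ifelse(n >= 2, 1, 0))
  ch <- simulate_birth_death_chain(ls2, k_plus = 1, n0 = 1, n_events = 1e5,
                                   size_max = 2, seed = 42)
  t1 <- sum(ch$holding_s[ch$size == 1])
  t2 <- sum(ch$holding_s[ch$size == 2])
  ratio <- t2 / t1
  # block-wise standard error of the occupancy ratio
  blocks <- split(seq_len(nrow(ch)), cut(seq_len(nrow(ch)), 20))
  br <- vapply(blocks, function(i) {
    sum(ch$holding_s[i][ch$size[i] == 2]) / sum(ch$holding_s[i][ch$size[i] == 1])
  }, numeric(1))
  se <- stats::sd(br) / sqrt(length(br))
  expect_lt(abs(ratio - exp(-1)), 3 * se + 1e-9)
})

test_that("stationary occupancies over sizes 1..5 satisfy detailed balance", {
  ls <- free_energy_landscape("custom", custom_fn = function(n) 0.4 * n)
  ch <- simulate_birth_death_chain(ls, n_events = 2e5, size_max = 5, seed = 7)
  occ <- tapply(ch$holding_s, factor(ch$size, levels = 1:5), sum)
  occ <- occ / sum(occ)
  theo <- exp(-0.4 * (1:5)); theo <- theo / sum(theo)
  blocks <- split(seq_len(nrow(ch)), cut(seq_len(nrow(ch)), 20))
  for (k in 1:5) {
    br <- vapply(blocks, function(i) {
      sum(ch$holding_s[i][ch$size[i] == k]) / sum(ch$holding_s[i])
    }, numeric(1))
    se <- stats::sd(br) / sqrt(length(br))
    expect_lt(abs(occ[k] - theo[k]), 3 * se + 1e-9)
  }
})

test_that("the inhibited preset never exceeds the 600-molecule cap", {
  for (s in 1:3) {
    sim <- small_movie_sim(seed = s, n_frames = 15, preset = "inhibited")
    expect_lte(max(sim$truth$n_true), 600)
  }
})

test_that("flat landscape with zero attachment rate freezes all trajectories", {
  ls <- free_energy_landscape("custom", custom_fn = function(n) rep(0, length(n)))
  cfg <- sim_config(landscape = ls, k_plus = 0, n_frames = 8,
                    n_clusters_init = 5, diffusion_D = 0, seed = 3)
  sim <- simulate_cluster_dynamics(cfg)
  per <- tapply(sim$truth$n_true, sim$truth$cluster_id, function(x) length(unique(x)))
  expect_true(all(per == 1L))
})

test_that("a landscape with interior NaN or undeclared non-finite values is rejected", {
  bad <- free_energy_landscape("custom", custom_fn = function(n) ifelse(n == 3, NaN, 0))
  expect_error(simulate_cluster_dynamics(sim_config(landscape = bad, n_frames = 2, seed = 1)),
               "NA|NaN")
  undeclared <- free_energy_landscape("custom",
    custom_fn = function(n) ifelse(n == 3, Inf, 0))
  expect_error(precondensate:::landscape_table(undeclared, 10), "wall")
})

test_that("identical config and seed give identical ground truth and stack", {
  cfg <- sim_config(n_frames = 5, n_clusters_init = 4, field_size = c(64, 64), seed = 9)
  s1 <- simulate_cluster_dynamics(cfg)
  s2 <- simulate_cluster_dynamics(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(render_movie(s1), render_movie(s2))
})

test_that("labelled counts are a thinning at the labelling fraction", {
  # across seeds, mean n_gfp / n converges to label_fraction
  ratios <- sizes <- c()
  for (s in 1:12) {
    cfg <- sim_config(n_frames = 3, n_clusters_init = 10, n_init_max = 400, seed = s)
    sim <- simulate_cluster_dynamics(cfg)
    f1 <- sim$truth[sim$truth$frame == 1L, ]
    ratios <- c(ratios, f1$n_gfp_true)
    sizes <- c(sizes, f1$n_true)
  }
  p_hat <- sum(ratios) / sum(sizes)
  se <- sqrt(0.2 * 0.8 / sum(sizes))
  expect_lt(abs(p_hat - 0.2), 3 * se)
  # and never more labels than molecules
  expect_true(all(ratios <= sizes))
})

test_that("Boltzmann sampler matches enumerated probabilities", {
  ls <- free_energy_landscape("custom", custom_fn = function(n) 0.3 * n)
  set.seed(1)
  x <- sample_boltzmann(ls, 2e4, size_max = 6)
  p_hat <- tabulate(x, 6) / 2e4
  p <- exp(-0.3 * (1:6)); p <- p / sum(p)
  expect_lt(max(abs(p_hat - p)), 4 * sqrt(max(p * (1 - p)) / 2e4))
})

test_that("ground-truth nucleation is recorded for coalescence-driven growth", {
  cfg <- sim_config(coalescence = TRUE, n_frames = 150, n_clusters_init = 30,
                    n_init_max = 150, diffusion_D = 0.02, seed = 1)
  sim <- simulate_cluster_dynamics(cfg)
  expect_gt(nrow(sim$merges), 0)
  nuc <- sim$nucleation
  expect_true(!is.na(nuc$condensate_id))
  # the condensate stays above the critical size from the nucleation frame on
  ct <- sim$truth[sim$truth$cluster_id == nuc$condensate_id &
                    sim$truth$frame >= nuc$nucleation_frame, ]
  expect_true(all(ct$n_true > nuc$critical_n))
})
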