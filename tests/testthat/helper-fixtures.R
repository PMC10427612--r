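# Shared fixtures, generated in code.

# small rendered movie with known ground truth
small_movie_sim <- function(seed = 11, n_frames = 10, preset = "inhibited") {
  cfg <- sim_config(landscape = free_energy_landscape(preset),
                    n_frames = n_frames, n_clusters_init = 6,
                    field_size = c(128, 128), seed = seed)
  simulate_cluster_dynamics(cfg)
}

# a single bright, centred, static cluster (direct truth construction so the
# size is deterministic)
one_spot_sim <- function(n_true = 300, field = 96, n_frames = 1, seed = 5,
                         shot_noise = TRUE) {
  cfg <- sim_config(n_frames = n_frames, n_clusters_init = 1,
                    field_size = c(field, field), shot_noise = shot_noise,
                    diffusion_D = 0, seed = seed)
  centre <- field * cfg$pixel_size / 2
  truth <- tibble::tibble(
    frame = seq_len(n_frames), cluster_id = 1L,
    n_true = n_true, n_gfp_true = round(n_true * cfg$label_fraction),
    x_um = centre, y_um = centre)
  structure(list(config = cfg, truth = truth,
                 merges = tibble::tibble(frame = integer(), from_id = integer(),
                                         into_id = integer())),
            class = "cluster_sim")
}

# brute-force minimal assignment cost by permutation enumeration
brute_lap_cost <- function(C) {
  n <- nrow(C)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) best <- min(best, sum(C[cbind(seq_len(n), p)]))
  best
}
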