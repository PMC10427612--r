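# precondensate

Quantifying pre-condensate protein clusters in living cells.

Before a biomolecular condensate nucleates, fluorescently tagged proteins in
the nucleus form small, mobile clusters whose sizes fluctuate near the
detection limit of live-cell microscopy. This package implements the full
quantitative chain for analysing such data — and, because raw single-cell
movies are large and idiosyncratic, a synthetic-data generator with exact
ground truth so every stage can be validated end to end:

* **simulation** — kinetic (Gillespie) birth–death cluster dynamics on a
  configurable free-energy landscape with detailed balance, optional
  coalescence, partial (1-in-5) labelling, Gaussian-PSF rendering with
  Poisson + read noise to 16-bit TIFF stacks, stepwise photobleaching
  traces, and fractional-Brownian single-particle tracks;
* **segmentation & tracking** — difference-of-Gaussians bandpass, robust
  global threshold, 8-connected components with half-maximum area
  refinement; optimal bipartite (Jonker–Volgenant) frame-to-frame linking
  with gap memory and merge handling;
* **molecule counting** — photobleaching step counting (greedy change-point
  fitting with counter-fit acceptance) giving the dense-phase density
  ρ ≈ 29 labelled molecules/µm², and the calibration chain
  `area × ρ → labelled count`, `÷ f_label (1/5) → total count`,
  `÷ (f_label · f_focal) = ×25 → whole-nucleus count`;
* **nucleation analysis** — per-cell critical sizes (the largest area a
  non-condensing cluster reaches), pre/post-nucleation splitting, lag-time
  dispersion, and the Landau free-energy landscape
  `ΔG_n = −k_BT ln(p_n / n p_1)` from monomer occupancies, with 99%
  bootstrap confidence bands (resampling whole tracks) and a fit of the
  initial surface scaling `ΔG ≈ A n^β` (β ≈ 2/3);
* **growth diagnostics** — the mean cluster-size gradient
  `∇_size(j) = (1/n_j) Σ |area_i − area_{i−1}|`, its size-normalised
  distribution (coalescence vs Ostwald ripening), and the small-cluster
  occupancy trend;
* **diffusion** — time-averaged MSDs per track with free (`4Dt`) and
  generalised (`4Dt^α`) fits and sub/free/directed classification.

Everything is a plain data frame in and a tibble out; results have
`tidy()`/`glance()` methods and `autoplot()`s.

## Worked example

```r
library(precondensate)

# calibration arithmetic
cal <- calibration_model()
cal
#> <calibration_model> rho = 29 um^-2, f_label = 0.2, f_focal = 0.2 (x25 nucleus factor)
round(area_to_gfp(14, cal))      # a 14 um^2 cluster holds ~406 labelled molecules
gfp_to_total(406, cal)           # ... i.e. ~2030 molecules in total
nucleus_total(1000, cal)         # 1000 focal-plane labels -> 25000 nuclear molecules

# one synthetic stressed cell, full pipeline
cfg <- sim_config(n_frames = 40, seed = 42)
res <- run_pipeline(cfg, n_boot = 2000)
res$critical
#> # A tibble: 1 x 4
#>   cell_id condensate_id critical_area_um2 critical_n
#> 1       1             4              2.51       364.
head(dplyr::filter(tibble::as_tibble(res$landscape), n_obs > 0), 5)
#>        n dG_kT  ci_low ci_high dG_point n_obs censored
#> 1   6.93 0      0         0       0        23 FALSE
#> 2  10.8  0.857  0.0543    1.69    0.853    17 FALSE
#> 3  16.7  1.73   0.660     3.91    1.65     11 FALSE
#> 4  25.5  1.24   0.348     2.34    1.22     26 FALSE
#> 5  38.8  0.847 -0.0348    1.85    0.823    59 FALSE
autoplot(res$landscape)

# density calibration from simulated fixed-cell bleaching traces
estimate_density(simulate_fixed_cell_traces(n_regions = 50, seed = 1))
#> <density_estimate> rho = 29.00 +/- 0.09 molecules/um^2 (50 regions, 451 steps)

# surface-scaling exponent from a Boltzmann-sampled ensemble
ls <- free_energy_landscape("custom", custom_fn = function(n) 0.5 * n^(2/3))
set.seed(7)
fel <- free_energy(monomer_occupancy(sample_boltzmann(ls, 30000, size_max = 400)))
fit_initial_scaling(fel, offset = "monomer")
#> <scaling_fit> dG ~ 0.495 * n^0.669 over 10 bins (R^2 = 1.000)
```

Reading the numbers: the cell's critical size (the largest area any
non-condensing cluster reached) is 2.5 µm² ≈ 364 molecules; the landscape is
pinned to ΔG = 0 at the smallest detectable size class and rises by a few
k_BT with wide 99% bands from only one small movie; the density estimate
recovers the generator's 29 µm⁻² almost exactly; and the scaling fit
recovers the 2/3 surface exponent (fitted 0.669) and amplitude (0.495 vs
0.5) of the sampling landscape.

A thin command-line wrapper over the same functions lives at
`inst/cli/precondensate` (subcommands `simulate`, `segment`, `track`,
`steps`, `calibrate`, `landscape`, `growth`, `diffusion`, `all`).

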