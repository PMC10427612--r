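---
title: "Quantifying pre-condensate protein clusters: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pre-condensate protein clusters: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(precondensate)
```

# The scientific problem

Biomolecular condensates — large membraneless assemblies formed by phase
separation — are usually studied near their final, stable state. What happens
*before* a condensate nucleates is much harder to observe: in living cells,
fluorescently tagged proteins form small, mobile, transient clusters whose
sizes fluctuate near the detection limit of live-cell microscopy. Classical
nucleation theory predicts that such pre-critical clusters should be rare and
tiny; recent work suggests instead a broad population of long-lived clusters
and a surprisingly flat free-energy landscape.

`precondensate` implements the full quantitative chain for this kind of
experiment:

1. **calibration** — fixed-cell photobleaching step counting gives a
   dense-phase labelled-molecule density $\rho$ (molecules per
   $\mu\mathrm{m}^2$), which converts segmented cluster areas into molecule
   counts, with corrections for partial labelling and for the fraction of the
   nucleus inside the focal plane;
2. **segmentation and tracking** of cluster regions in live-cell movies;
3. **per-cell critical sizes** and the pre-/post-nucleation split;
4. the **Landau free-energy landscape** of cluster sizes
   $\Delta G_n = -k_BT \ln\!\big(p_n / (n\,p_1)\big)$ with bootstrap
   confidence bands and a fit of the initial scaling $\Delta G \sim A n^\beta$;
5. **growth-mechanism diagnostics** (Ostwald ripening versus coalescence)
   from the mean cluster-size gradient
   $\nabla_{\mathrm{size}}(j) = \frac{1}{n_j}\sum_{i=2}^{n_j}
   |\mathrm{area}_i - \mathrm{area}_{i-1}|$;
6. **diffusion classification** from time-averaged mean squared
   displacements, $\langle r^2\rangle = 4Dt$ and
   $\langle r^2\rangle = 4Dt^\alpha$.

Because raw single-cell movies are large and idiosyncratic, the package ships
a first-class **synthetic-data generator** with exact ground truth: every
analysis stage is validated end to end against data whose true cluster sizes,
positions, labelled counts, bleaching steps and nucleation times are known.

# The cluster-size model

## Free-energy landscape and birth–death kinetics

Cluster sizes $n$ (total molecules, labelled plus unlabelled) evolve as a
continuous-time birth–death chain on a landscape $\Delta G_n$ (in units of
$k_BT$). Monomer attachment occurs at a constant rate $k_+$; detachment from
a cluster of size $n$ at
$k_-(n) = k_+\, e^{\Delta G_n - \Delta G_{n-1}}$,
so detailed balance holds with respect to the Boltzmann weight
$e^{-\Delta G_n}$, and long-run occupancies are exactly the equilibrium
distribution of the landscape. The chain is integrated by Gillespie sampling
between frames; only frame-sampled sizes are emitted, matching the 10-s (or
30-s) acquisition cadence of live-cell imaging.

Three presets encode the experimental regimes:

* **stressed** — a surface-dominated rise $\Delta G_n = c\,n^{2/3}$ up to a
  plateau onset $n_p$, constant beyond it. Defaults $c = 0.5\,k_BT$,
  $n_p = 27$ are package choices (the plateau then sits near
  $4.5\,k_BT$), selected so that equilibrium cluster sizes are broadly
  distributed from monomers to hundreds of molecules, as observed in stressed
  cells. They are not measured values.
* **unstressed** — the same rise with a hard wall at `wall_size` (default
  150): the landscape effectively diverges and no cluster grows past the
  wall, emulating blocked nucleation in unstressed cells.
* **inhibited** — the stressed shape with a hard cap at 600 molecules,
  emulating kinase-inhibited cells in which no large clusters form. The cap
  applies to the *true* size by construction.

Monomer-scale thermodynamics deserves one remark: the occupancy estimator
(below) pins $\Delta G = 0$ at its reference class, so all landscapes here
are reported *relative to the smallest detectable class*, and the presets are
likewise normalised to $\Delta G_1 = 0$.

## Coalescence, steric exclusion, and condensate growth

On a plateau, single-molecule attachment produces only diffusive size drift
— far too slow for the fast, irreversible condensate growth seen after
nucleation. The growth mechanism supported by the gradient analysis is
**coalescence**: large clusters sweep up smaller ones. The generator
therefore offers optional pairwise coalescence (off by default): clusters
whose surfaces approach within `contact_radius` (default 0.8 µm) fuse,
summing sizes and labelled counts, with the merge recorded in the ground
truth. Nucleating, stressed-cell scenarios enable coalescence; equilibrium
occupancy studies leave it off.

When coalescence is *off*, droplets are kept apart by steric exclusion at the
same contact margin. Physically, two dense-phase droplets cannot
interpenetrate (in reality they would fuse); practically, the margin is wide
enough that the point-spread-function halos of neighbouring clusters do not
bridge into a single segmented region, which would otherwise contaminate
size statistics with optical-overlap artefacts.

## Labelling

Roughly one molecule in five carries the fluorescent tag (a tagged copy
expressed at ~25% of the endogenous level gives $0.25/1.25 = 0.2$ of all
molecules). The generator tracks the labelled count $n_\mathrm{gfp}$ through
the dynamics: each attachment is labelled with probability `label_fraction`,
each detachment removes a labelled molecule with probability
$n_\mathrm{gfp}/n$. This keeps $n_\mathrm{gfp} \le n$ always, and
$E[n_\mathrm{gfp}/n] =$ `label_fraction`.

# Rendering model

Each cluster is drawn as a filled disc whose **footprint follows the total
size**: area $= n \cdot f_\mathrm{label} / \rho$, so the labelled density in
the dense phase equals $\rho$ (default 29 µm⁻²) in expectation and the
area-based calibration $n = \mathrm{area}\cdot\rho/f_\mathrm{label}$ inverts
the rendering exactly. Labelling stochasticity appears where it belongs — in
the disc's *brightness* ($n_\mathrm{gfp}\times$ `poisson_gain` expected
camera counts) — not in its footprint; this mirrors the robustness of
area-based size estimates in the real experiment, where the cluster outline
is set by all molecules while photon counts fluctuate with the labels. The
photon image is convolved with a Gaussian PSF (σ 0.12 µm at 0.16-µm pixels),
photobleached exponentially if requested, offset by a constant background,
and corrupted by Poisson shot noise plus Gaussian read noise before 16-bit
quantisation. `poisson_gain = 150` counts per labelled molecule is an
EMCCD-scale choice that renders clusters above ~4 pixels reliably detectable
at the default noise level.

Sub-resolution clusters (disc radius under half a pixel) deposit their
photons into the nearest pixel. No nuclear substructure, 3-D optics or
z-sectioning is simulated.

# Segmentation and tracking

Segmentation is deterministic: a difference-of-Gaussians bandpass (σ = 1 and
20 px), a global threshold, 8-connected labelling, and a 2-pixel minimum
area. The default threshold is a **robust noise floor** (median + 4 MAD of
the bandpassed image). Otsu's method is available as an option but is not the
default: with a bright condensate in frame, Otsu places the threshold near
half the condensate level and misses the faint clusters that matter most
here, while the noise floor detects faint and bright spots alike and returns
zero regions on object-free frames.

The exact threshold value biases areas (a low threshold includes the PSF
halo), so areas of resolved regions (≥ 12 px) are refined at **half the
region's plateau level**: the half-maximum contour of a PSF-blurred uniform
disc coincides with the disc edge, making the refined area insensitive to
the detection threshold. Sub-resolution regions keep their thresholded pixel
count — their area is optics-limited regardless.

Tracks are built frame to frame by optimal bipartite assignment on squared
centroid displacement (an exact Jonker–Volgenant solver, validated against
brute-force enumeration), with links gated at `max_disp_um` (default 2 µm —
comfortably above the ~0.6 µm per-frame diffusion step at the default
$D = 0.005\,\mu\mathrm{m}^2/\mathrm{s}$ and 10-s frames; a tighter gate
fragments tracks). Unmatched tracks survive `memory_frames` (default 2)
missed frames; empty frames age the memory too. When a track loses its
region but ends within the gate of a region claimed by another track, a
merge is recorded and the larger antecedent keeps its identity.

# Photobleaching step counting and density calibration

`count_steps()` fits a piecewise-constant staircase by greedy bisection:
each new step is the single change point that most reduces the residual sum
of squares. Three rules govern model size:

* a placed step is kept only if its placement-time RSS gain exceeds
  $4\hat\sigma^2\ln N$, a scan-statistic threshold with the noise variance
  $\hat\sigma^2$ estimated robustly from successive differences (median
  absolute difference / $\sqrt2\,\Phi^{-1}(0.75)$), which makes the rule
  invariant to affine rescaling of the trace;
* interior plateaus shorter than `min_plateau` (4 frames) are treated as
  split artefacts of a single step and merged — bleach events closer than
  this are counted as one larger step (the resolution limit of the method);
* the accepted staircase must beat a **counter-fit** with the same number of
  steps placed at plateau midpoints by at least `acceptance_ratio` (default
  1) in RSS — a staircase-shaped signal is fitted far better at its true
  change points than between them, while pure noise is not.

Both upward and downward level changes are fitted, but only downward steps
count as bleaching events; upward excursions (blinking) are reported
separately. On noiseless staircases the fit is exact; at signal-to-noise 5
the count is exact in ≥ 95% of simulated traces for 3, 5 and 15 steps.

The dense-phase density pools counts over regions,
$\hat\rho = \sum_j s_j / \sum_j a_j$, with a bootstrap (resampling regions)
standard error. The fixed-cell generator draws 3–15 labelled molecules per
region with areas $n_\mathrm{gfp}/\rho$, dwell times exponential in the
number of unbleached fluorophores (rate $k\times$ `bleach_rate`) with a
5-frame minimum dwell: faster double-bleaches are merged by camera
integration and are not treated as resolvable.

# Calibration

With $\rho = 29\ \mu\mathrm{m}^{-2}$, $f_\mathrm{label} = 1/5$ and
$f_\mathrm{focal} = 1/5$ (a ~1-µm focal depth in a ~7-µm nucleus):

* area → labelled molecules: $\times\, \rho$ (14 µm² ↦ ≈ 400);
* labelled → total molecules: $\div\, f_\mathrm{label}$ (400 ↦ 2000);
* focal-plane labelled count → whole-nucleus total:
  $\div\,(f_\mathrm{label} f_\mathrm{focal}) = \times 25$
  (1000 ↦ 25{,}000; 5000 ↦ 125{,}000).

Counts stay real-valued internally and are rounded only for reporting. A
per-timepoint density override exists but defaults to a constant, since the
measured dense-phase density is essentially time-invariant.

# Critical sizes, nucleation, and the landscape

**Critical size.** Per cell, the critical area is the largest area ever
reached by any track *not* in the condensate lineage — the size up to which
clusters still fluctuate dynamically. The condensate is the track with the
largest final area, accepted only if it has clearly outgrown every other
track (running maximum ≥ 1.3× the best of the rest) and has not collapsed
(final ≥ 0.8× its own maximum). Both factors are package choices: the
experiment identifies condensates visually, and any automatic rule must
discriminate a genuinely nucleated cluster from the largest member of a
fluctuating ensemble. When two clusters grow comparably the identification
is ambiguous; downstream comparisons should condition on an unambiguous
condensate (the tests do).

**Nucleation frame.** The earliest frame at which the condensate lineage
exceeds the cell's critical area and never falls below it again; earlier
observations are pre-nucleation, later ones post-nucleation. Lag times are
nucleation times relative to movie start; their coefficient of variation
across cells quantifies the stochasticity of nucleation (broad lag
distributions are the hallmark of nucleation-and-growth).

**Occupancy and free energy.** The monomer occupancy of a size class is the
probability that a randomly chosen *molecule* sits in a cluster of that
class: $p(\mathrm{bin}) = \sum_{i \in \mathrm{bin}} n_i / \sum_i n_i$. Size
classes are logarithmically spaced integer bins (growth factor 1.5,
geometric-mean centres; the smallest sizes get width-1 bins automatically).
Before applying
$\Delta G_n = -\ln\!\big(p_n/(n\,p_1)\big)$, each bin's probability is
divided by the number of integer sizes it spans, so bin widths do not
distort the landscape; for width-1 bins this reduces exactly to the formula.
The reference is the smallest populated class — true monomers are below the
detection limit, so in calibrated data the reference is one labelled
molecule ≈ 5 total molecules — and $\Delta G$ at the reference is zero by
construction. Empty or sparsely populated bins (< 5 observations) are
flagged censored: within experimental resolution the free energy there
effectively diverges.

**Bootstrap bands.** Confidence intervals resample whole *tracks* with
replacement (respecting within-track autocorrelation), 10,000 replicates and
percentile 99% intervals by default; the centre line is the mean over
replicates. The implementation precomputes a track-by-bin molecule-mass
matrix, so each replicate is a single weighted column sum and the full
10,000-replicate band takes well under a second. In simulation the 99% bands
cover the enumerated true landscape in ≥ 97% of replications.

**Initial scaling.** The rise of the landscape is fitted as
$\ln\Delta G = \ln A + \beta\ln n$ over bins below the plateau onset (located
automatically as the first bin where the local log-log slope falls below
half the initial slope). One subtlety: because the estimator pins
$\Delta G = 0$ at the reference, a landscape whose absolute form is
$A n^\beta$ appears as $A(n^\beta - 1)$, which is *not* a pure power law at
small $n$ — a log-log fit on it overestimates $\beta$ by ~0.15. The `offset`
argument therefore selects between the pure power law (`"none"`), the
monomer-referenced model $A(n^\beta-1)$ fitted by nonlinear least squares
(`"monomer"`), or an automatic choice by residual sum of squares (the
default). For recovery of a generator exponent the monomer-referenced model
is the consistent one.

# Growth diagnostics

The mean size gradient uses the divisor $n_j$ (the number of frames the
cluster was identified) even though only $n_j - 1$ differences are summed;
that convention is kept as printed. Dividing by the track's mean area gives
a normalized gradient: under coalescence-driven growth the absolute gradient
scales with cluster size and the normalized gradient is flat across size
deciles; under stepwise monomer exchange the absolute gradient is
size-independent and the normalized gradient falls with size.
`ostwald_diagnostic()` tracks the share of molecules in clusters below the
critical size frame by frame: Ostwald ripening drains mid-sized clusters
into the largest one (a negative trend with a transient small-cluster
excess), whereas coalescence removes small clusters wholesale with no such
transient.

# Diffusion analysis

MSDs are time-averaged within each track over all ordered pairs, with lags
up to a quarter of the track length (longer lags of a single-track MSD are
dominated by estimator variance). The free fit is a least-squares slope
through the origin ($D = $ slope/4); the generalised fit is linear in
log–log space, yielding $\alpha$ and a generalised $D$; motion is classified
sub-diffusive below $\alpha = 0.8$, directed above $\alpha = 1.2$ (tolerance
0.2, a package default). Tracks shorter than 10 frames are excluded with a
logged reason. The track generator produces exact fractional Brownian motion
per coordinate (Hosking's recursion on the fGn covariance, Hurst index
$\alpha/2$), so time-averaged MSDs follow $4Dt^\alpha$ in expectation;
$\alpha = 2$ is the deterministic ballistic limit with speed $2\sqrt D$.
Single-track exponent estimates carry sd ≈ 0.1 at 300 frames — ensemble
means, not single tracks, recover $\alpha$ to better than 0.1.

# Worked example

A small end-to-end run (sizes here are chosen so the vignette's code is
cheap; the package defaults simulate 12 clusters on 256×256 px for 100
frames):

```{r example, eval = FALSE}
cfg <- sim_config(n_frames = 30, field_size = c(128, 128),
                  n_clusters_init = 8, seed = 42)
res <- run_pipeline(cfg, out_dir = "demo_out", n_boot = 2000)

res$critical          # per-cell critical area and molecule count
res$landscape         # dG_n with 99% bootstrap bands
autoplot(res$landscape)
fit_initial_scaling(res$landscape, offset = "monomer")
glance(estimate_density(simulate_fixed_cell_traces(n_regions = 50, seed = 1)))
```

`run_pipeline()` writes the movie (16-bit TIFF), ground truth, calibrated
track table, landscape, growth and diffusion summaries, a flat key=value
config, and a manifest (package version, seed, config hash); identical
config and seed reproduce every output byte for byte.

# Numerical choices and degenerate inputs

* Ties in track assignment are broken by the assignment solver's column
  order (lowest index); merge events keep the larger antecedent's id.
* Coordinates are 0-based pixel indices with the origin at the top-left
  pixel centre; x runs right, y runs down; centroids are
  intensity-weighted.
* Constant images segment to zero regions; constant traces fit zero steps;
  stationary tracks have identically zero MSD; `n_boot = 1` collapses the
  bootstrap band onto the single replicate; a cell whose only track is the
  condensate has a *missing* (not zero) critical size.
* Landscapes returning `NA`/`NaN`, or `Inf` at an interior size without a
  declared wall, reject the configuration outright.
* All stochastic stages consume one explicit seed from the configuration;
  the renderer derives an independent stream (seed + 1) so that dynamics and
  imaging noise are separately reproducible.

# What the synthetic data does and does not establish

The generator emulates the *statistical structure* of the experiment:
birth–death size dynamics on a configurable landscape, partial labelling,
disc + Gaussian-PSF rendering with Poisson and read noise, stepwise
bleaching, anomalous centroid motion, coalescence. Passing tests therefore
establish that the estimators are correct and well-calibrated *given that
model*. Real movies contain features the generator omits — nuclear
substructure and uneven background, focus drift, non-circular clusters,
motion blur, interactive-segmentation idiosyncrasies — so agreement on
synthetic data bounds estimator error, not total experimental error.
Known limitations worth restating:

* sizes below the optical resolution floor (a few pixels, ≈ tens of
  molecules at the default calibration) are reported at the optics' scale,
  not the cluster's: the first landscape bins reflect the PSF;
* condensate identification is ambiguous when two clusters grow comparably;
* the test-suite problem sizes (movies of 25–150 frames, 128–256 px fields,
  hundreds of bootstrap ensembles, 200-replication coverage studies) are the
  package's chosen validation scale — estimator behaviour at much larger
  data volumes is extrapolation.
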