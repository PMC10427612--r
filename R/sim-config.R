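#' Simulation configuration for synthetic cluster movies
#'
#' Bundles every parameter of the synthetic-data generator: the free-energy
#' landscape, attachment kinetics, imaging geometry and optics, labelling and
#' noise. Defaults emulate live-cell HILO imaging of GFP-tagged nuclear
#' protein clusters: 160-nm pixels, 10-s frame interval, a dense-phase
#' labelled-molecule density of 29 per square micron, and one-in-five
#' labelling.
#'
#' @param landscape A [free_energy_landscape()] object (or preset name).
#' @param k_plus Monomer attachment rate per cluster (s^-1). Detachment rates
#'   follow from detailed balance with respect to the landscape.
#' @param n_clusters_init Number of clusters simulated per cell.
#' @param n_init_max Upper truncation of the initial (metastable Boltzmann)
#'   size ensemble; also capped by any hard wall of the landscape.
#' @param monomer_pool Total molecule budget across all clusters; attachment
#'   pauses while the budget is exhausted. `Inf` disables the constraint.
#' @param frame_interval Time between frames (s).
#' @param n_frames Number of frames.
#' @param pixel_size Pixel edge (um).
#' @param field_size Image size in pixels, length-2 (width, height).
#' @param psf_sigma Gaussian PSF standard deviation (um).
#' @param gfp_density_rho Dense-phase labelled-molecule density (um^-2); a
#'   cluster of `n` total molecules is rendered with footprint
#'   `n * label_fraction / rho` so that the labelled density in the dense
#'   phase equals `rho` in expectation.
#' @param label_fraction Fraction of molecules carrying the fluorescent tag.
#' @param focal_fraction Fraction of nuclear molecules within the focal plane
#'   (used for whole-nucleus extrapolation, not by the renderer).
#' @param photobleach_rate Exponential intensity decay per frame.
#' @param poisson_gain Expected camera counts per labelled molecule.
#' @param read_noise_sd Additive Gaussian read noise (counts).
#' @param shot_noise Apply Poisson shot noise (and read noise)? Disable for
#'   noise-free reference renders.
#' @param background Constant background offset (counts).
#' @param diffusion_D Cluster centroid diffusion coefficient (um^2 s^-1).
#' @param diffusion_alpha Anomalous exponent for centroid motion.
#' @param coalescence Allow pairwise merging of clusters that approach within
#'   `contact_radius`? Off by default.
#' @param contact_radius Surface-to-surface contact margin (um): the merge
#'   distance when coalescence is on, and the minimum rendered gap between
#'   droplets kept apart by steric exclusion when it is off (wide enough
#'   that PSF halos of neighbouring clusters do not bridge).
#' @param seed Integer seed; a fixed seed makes every output byte-identical.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_frames = 20, seed = 1)
#' cfg$landscape$preset
#' @export
sim_config <- function(landscape = free_energy_landscape("stressed"),
                       k_plus = 1,
                       n_clusters_init = 12,
                       n_init_max = 600,
                       monomer_pool = Inf,
                       frame_interval = 10,
                       n_frames = 100,
                       pixel_size = 0.16,
                       field_size = c(256, 256),
                       psf_sigma = 0.12,
                       gfp_density_rho = 29,
                       label_fraction = 0.2,
                       focal_fraction = 0.2,
                       photobleach_rate = 0,
                       poisson_gain = 150,
                       read_noise_sd = 2,
                       shot_noise = TRUE,
                       background = 100,
                       diffusion_D = 0.005,
                       diffusion_alpha = 1,
                       coalescence = FALSE,
                       contact_radius = 0.8,
                       seed = 1L) {
  if (is.character(landscape)) landscape <- free_energy_landscape(landscape)
  stopifnot(inherits(landscape, "fel_landscape"))
  num_pos <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
  if (!num_pos(k_plus) && k_plus != 0) stop("k_plus must be a non-negative number", call. = FALSE)
  stopifnot(
    n_clusters_init >= 1, n_init_max >= 1, monomer_pool > 0,
    num_pos(frame_interval), n_frames >= 1,
    num_pos(pixel_size), length(field_size) == 2L, all(field_size >= 8),
    num_pos(psf_sigma), num_pos(gfp_density_rho),
    is.numeric(label_fraction), label_fraction > 0, label_fraction <= 1,
    is.numeric(focal_fraction), focal_fraction > 0, focal_fraction <= 1,
    photobleach_rate >= 0, num_pos(poisson_gain), read_noise_sd >= 0,
    background >= 0, diffusion_D >= 0,
    diffusion_alpha > 0, diffusion_alpha <= 2,
    num_pos(contact_radius)
  )
  structure(
    list(landscape = landscape, k_plus = k_plus,
         n_clusters_init = as.integer(n_clusters_init),
         n_init_max = as.integer(n_init_max),
         monomer_pool = monomer_pool,
         frame_interval = frame_interval, n_frames = as.integer(n_frames),
         pixel_size = pixel_size, field_size = as.integer(field_size),
         psf_sigma = psf_sigma, gfp_density_rho = gfp_density_rho,
         label_fraction = label_fraction, focal_fraction = focal_fraction,
         photobleach_rate = photobleach_rate, poisson_gain = poisson_gain,
         read_noise_sd = read_noise_sd, shot_noise = isTRUE(shot_noise),
         background = background,
         diffusion_D = diffusion_D, diffusion_alpha = diffusion_alpha,
         coalescence = isTRUE(coalescence), contact_radius = contact_radius,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  landscape preset :", x$landscape$preset, "\n")
  cat("  clusters / frames:", x$n_clusters_init, "/", x$n_frames,
      sprintf("(dt = %gs)", x$frame_interval), "\n")
  cat("  field            :", paste(x$field_size, collapse = " x "),
      sprintf("px @ %g um", x$pixel_size), "\n")
  cat("  rho, f_label     :", x$gfp_density_rho, "um^-2,", x$label_fraction, "\n")
  cat("  coalescence      :", x$coalescence, " seed:", x$seed, "\n")
  invisible(x)
}
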