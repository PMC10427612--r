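#' Calibration model for molecule counting
#'
#' Holds the three constants that convert segmented areas into molecule
#' numbers: the dense-phase labelled-molecule density `rho` (from fixed-cell
#' photobleaching, ~29 per square micron), the labelling fraction `f_label`
#' (about one in five molecules carries the tag: a tagged copy expressed at
#' ~25% of the endogenous level gives 0.25/1.25 = 0.2 of all molecules), and
#' the focal-plane fraction `f_focal` (a ~1-um focal depth in a ~7-um nucleus
#' captures about one fifth of the molecules). At the defaults, a focal-plane
#' labelled count converts to a whole-nucleus total by a factor
#' `1 / (f_label * f_focal) = 25`.
#'
#' @param rho Dense-phase labelled-molecule density (um^-2).
#' @param f_label Labelled fraction of total protein, in (0, 1].
#' @param f_focal Fraction of nuclear molecules in the focal plane, in (0, 1].
#' @return An object of class `calibration_model`.
#' @examples
#' cal <- calibration_model()
#' area_to_gfp(14, cal)      # ~400 labelled molecules
#' gfp_to_total(406, cal)    # ~2000 molecules in total
#' @export
calibration_model <- function(rho = 29, f_label = 0.2, f_focal = 0.2) {
  stopifnot(is.numeric(rho), rho > 0,
            is.numeric(f_label), f_label > 0, f_label <= 1,
            is.numeric(f_focal), f_focal > 0, f_focal <= 1)
  structure(list(rho = rho, f_label = f_label, f_focal = f_focal),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> rho = %g um^-2, f_label = %g, f_focal = %g (x%g nucleus factor)\n",
              x$rho, x$f_label, x$f_focal, 1 / (x$f_label * x$f_focal)))
  invisible(x)
}

#' Convert a cluster area to a labelled-molecule count
#'
#' `count = area * rho`. Counts are kept real-valued; round only at report
#' time.
#'
#' @param area_um2 Area(s) in square microns; must be non-negative.
#' @param model A [calibration_model()].
#' @return Numeric labelled-molecule count(s).
#' @export
area_to_gfp <- function(area_um2, model = calibration_model()) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(area_um2 < 0, na.rm = TRUE)) stop("area must be non-negative", call. = FALSE)
  area_um2 * model$rho
}

#' Convert a labelled-molecule count to a total molecule count
#'
#' `total = n_gfp / f_label` (x5 at the default one-in-five labelling).
#'
#' @param n_gfp Labelled count(s); must be non-negative.
#' @inheritParams area_to_gfp
#' @return Numeric total molecule count(s).
#' @export
gfp_to_total <- function(n_gfp, model = calibration_model()) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(n_gfp < 0, na.rm = TRUE)) stop("n_gfp must be non-negative", call. = FALSE)
  n_gfp / model$f_label
}

#' Extrapolate a focal-plane labelled count to the whole nucleus
#'
#' `total = n_gfp_focal / (f_label * f_focal)`; x25 at the defaults.
#'
#' @param n_gfp_focal Labelled molecules counted in the focal plane.
#' @inheritParams area_to_gfp
#' @return Whole-nucleus total molecule count(s).
#' @export
nucleus_total <- function(n_gfp_focal, model = calibration_model()) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(n_gfp_focal < 0, na.rm = TRUE)) stop("count must be non-negative", call. = FALSE)
  n_gfp_focal / (model$f_label * model$f_focal)
}

#' Append calibrated molecule counts to a track table
#'
#' Adds `n_gfp = area_um2 * rho` and `n_total = n_gfp / f_label` columns.
#'
#' @param tracks A track table with an `area_um2` column.
#' @inheritParams area_to_gfp
#' @return The track table with `n_gfp` and `n_total` appended.
#' @export
calibrate_tracks <- function(tracks, model = calibration_model()) {
  stopifnot(is.data.frame(tracks), "area_um2" %in% names(tracks))
  dplyr::mutate(tracks,
                n_gfp = area_to_gfp(.data$area_um2, model),
                n_total = gfp_to_total(.data$n_gfp, model))
}
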