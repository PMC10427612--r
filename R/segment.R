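#' Segment fluorescent cluster regions in one frame
#'
#' Deterministic spot segmentation: a difference-of-Gaussians bandpass
#' (small scale smooths pixel noise, large scale removes background and
#' uneven illumination), a global threshold (Otsu by default) on the
#' bandpassed image, 8-connected component labelling, and a minimum-area
#' filter. Areas of resolved regions (at least `refine_min_px` pixels) are
#' then refined at half the region's plateau level: the half-maximum contour
#' of a PSF-blurred uniform disc coincides with the disc edge, so this
#' de-biases areas against the exact global threshold value.
#'
#' @param image Numeric matrix (one grayscale frame, rows = y, cols = x).
#' @param pixel_size Pixel edge (um).
#' @param bandpass_sigmas Length-2: small and large Gaussian sigma in pixels.
#' @param threshold_method `"mad"` (default: a robust noise floor,
#'   median + 4 MAD of the bandpassed image, which detects faint and bright
#'   spots alike), `"otsu"` (global Otsu, floored at the same noise level:
#'   with very bright objects in frame Otsu tracks their half-level and
#'   misses faint spots), or a fixed numeric threshold on the bandpassed
#'   image.
#' @param min_area_px Discard components smaller than this many pixels.
#' @param refine_min_px Half-maximum area refinement is applied to regions
#'   with at least this many pixels (smaller spots are diffraction-limited
#'   and keep their thresholded pixel count).
#' @return A tibble of regions: `x_um`, `y_um` (intensity-weighted centroid,
#'   x right / y down from the top-left pixel centre), `area_um2`,
#'   `intensity` (integrated original intensity over the region), `n_px`.
#'   Zero rows for a blank or constant frame.
#' @examples
#' img <- matrix(0, 32, 32); img[10:14, 20:24] <- 50
#' segment_frame(img, pixel_size = 0.16)
#' @export
segment_frame <- function(image, pixel_size = 0.16,
                          bandpass_sigmas = c(1, 20),
                          threshold_method = "mad",
                          min_area_px = 2, refine_min_px = 12) {
  stopifnot(is.matrix(image), length(bandpass_sigmas) == 2L,
            bandpass_sigmas[1] < bandpass_sigmas[2])
  img <- image * 1.0
  bp <- fast_blur(img, bandpass_sigmas[1]) - fast_blur(img, bandpass_sigmas[2])

  rng <- range(bp)
  if (diff(rng) < .Machine$double.eps^0.5) return(empty_regions())

  floor_thr <- stats::median(bp) + 4 * stats::mad(bp)
  thr <- if (identical(threshold_method, "mad")) {
    floor_thr
  } else if (identical(threshold_method, "otsu")) {
    norm <- (bp - rng[1]) / diff(rng)
    thr_norm <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    # floored: on frames without bright objects Otsu merely splits noise
    max(rng[1] + thr_norm * diff(rng), floor_thr)
  } else {
    as.numeric(threshold_method)
  }
  mask <- bp > thr
  if (!any(mask)) return(empty_regions())

  lab <- label_components_8(mask)
  n_lab <- max(lab)
  if (n_lab == 0L) return(empty_regions())

  idx <- which(lab > 0L)
  lv <- lab[idx]
  w <- pmax(bp[idx], 0)
  row0 <- (idx - 1L) %% nrow(img)      # 0-based y
  col0 <- (idx - 1L) %/% nrow(img)     # 0-based x
  n_px <- tabulate(lv, n_lab)
  wsum <- rowsum_vec(w, lv, n_lab)
  wsum[wsum <= 0] <- NA_real_
  cx <- rowsum_vec(w * col0, lv, n_lab) / wsum
  cy <- rowsum_vec(w * row0, lv, n_lab) / wsum
  # fall back to unweighted centroid where weights vanish
  bad <- is.na(cx)
  if (any(bad)) {
    cx[bad] <- (rowsum_vec(col0, lv, n_lab) / n_px)[bad]
    cy[bad] <- (rowsum_vec(row0, lv, n_lab) / n_px)[bad]
  }
  inten <- rowsum_vec(img[idx], lv, n_lab)

  # half-maximum area refinement for resolved regions
  H <- nrow(img); Wd <- ncol(img)
  for (r in which(n_px >= refine_min_px)) {
    rr <- row0[lv == r]; cc <- col0[lv == r]
    plateau <- stats::quantile(bp[cbind(rr + 1L, cc + 1L)], 0.9, names = FALSE)
    if (plateau <= thr) next
    half <- plateau / 2
    i0 <- max(min(rr) - 3L, 0L); i1 <- min(max(rr) + 3L, H - 1L)
    j0 <- max(min(cc) - 3L, 0L); j1 <- min(max(cc) + 3L, Wd - 1L)
    sub <- bp[(i0:i1) + 1L, (j0:j1) + 1L, drop = FALSE]
    m2 <- label_components_8(sub >= half)
    seed_i <- round(cy[r]) - i0 + 1L; seed_j <- round(cx[r]) - j0 + 1L
    seed_i <- min(max(seed_i, 1L), nrow(m2)); seed_j <- min(max(seed_j, 1L), ncol(m2))
    comp <- m2[seed_i, seed_j]
    if (comp == 0L) {
      # centroid off-mask (odd shapes): take the component nearest the seed
      on <- which(m2 > 0L, arr.ind = TRUE)
      if (nrow(on) == 0L) next
      comp <- m2[on[which.min((on[, 1] - seed_i)^2 + (on[, 2] - seed_j)^2), , drop = FALSE]]
    }
    n_px[r] <- sum(m2 == comp)
  }

  out <- tibble::tibble(
    x_um = cx * pixel_size, y_um = cy * pixel_size,
    area_um2 = n_px * pixel_size^2,
    intensity = inten, n_px = n_px
  )
  dplyr::filter(out, n_px >= min_area_px)
}

# Gaussian blur dispatch: the in-package separable blur for small kernels,
# EBImage's compiled filter for the wide background scale.
fast_blur <- function(m, sigma) {
  brush <- 2L * ceiling(3 * sigma) + 1L
  if (sigma <= 3 || brush > min(dim(m))) return(gaussian_blur(m, sigma))
  out <- EBImage::gblur(EBImage::Image(m), sigma = sigma)
  matrix(as.numeric(EBImage::imageData(out)), nrow(m), ncol(m))
}

empty_regions <- function() {
  tibble::tibble(x_um = numeric(), y_um = numeric(), area_um2 = numeric(),
                 intensity = numeric(), n_px = integer())
}

rowsum_vec <- function(x, group, n) {
  out <- numeric(n)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# 8-connected labelling: EBImage::bwlabel gives 4-connected components; merge
# labels that touch diagonally via union-find on the label adjacency graph.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])), # down-right
    cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1]))  # up-right
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

#' Segment every frame of a movie
#'
#' Applies [segment_frame()] to each frame of an image stack and binds the
#' results with a `frame` column.
#'
#' @param movie A `cluster_movie` array or plain `H x W x F` numeric array.
#' @param pixel_size Pixel edge (um); defaults to the movie's config.
#' @param ... Passed to [segment_frame()].
#' @return A tibble of regions with a leading `frame` column.
#' @export
segment_movie <- function(movie, pixel_size = NULL, ...) {
  cfg <- attr(movie, "config")
  if (is.null(pixel_size)) {
    pixel_size <- if (!is.null(cfg)) cfg$pixel_size else 0.16
  }
  nf <- dim(movie)[3]
  purrr::map_dfr(seq_len(nf), function(f) {
    regs <- segment_frame(movie[, , f], pixel_size = pixel_size, ...)
    dplyr::mutate(regs, frame = f, .before = 1)
  })
}
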