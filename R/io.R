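#' Read and write movie stacks, track tables, traces and landscape tables
#'
#' Thin, schema-validated wrappers around `tiff` and `readr`. Movies are
#' multi-page 16-bit grayscale TIFF; tables are CSV with fixed column sets.
#'
#' @name precondensate-io
NULL

TRACK_COLS <- c("cell_id", "track_id", "frame", "time_s", "x_um", "y_um",
                "area_um2", "intensity")
TRUTH_COLS <- c("frame", "cluster_id", "x_um", "y_um", "n_true", "n_gfp_true")
TRACE_COLS <- c("frame", "intensity")
LANDSCAPE_COLS <- c("n", "dG_kT", "ci_low", "ci_high", "censored")

#' @param movie Integer array `H x W x F` (a `cluster_movie`).
#' @param path File path.
#' @rdname precondensate-io
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(is.array(movie), length(dim(movie)) == 3L)
  frames <- lapply(seq_len(dim(movie)[3]), function(f) movie[, , f] / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname precondensate-io
#' @export
read_movie_tiff <- function(path) {
  if (!file.exists(path)) stop("no such TIFF: ", path, call. = FALSE)
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                     error = function(e) {
                       stop("failed to read TIFF '", path, "': ",
                            conditionMessage(e), call. = FALSE)
                     })
  if (!is.list(frames)) frames <- list(frames)
  stack <- array(0L, dim = c(dim(frames[[1]]), length(frames)))
  for (f in seq_along(frames)) stack[, , f] <- as.integer(frames[[f]])
  structure(stack, class = c("cluster_movie", "array"))
}

check_schema <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' @param tracks Track table tibble.
#' @rdname precondensate-io
#' @export
write_track_table <- function(tracks, path) {
  check_schema(tracks, TRACK_COLS, "track table")
  readr::write_csv(tracks[, union(TRACK_COLS, names(tracks))], path)
  invisible(path)
}

#' @rdname precondensate-io
#' @export
read_track_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, TRACK_COLS, "track table")
  df
}

#' @param trace A `bleach_trace` or tibble with `frame`, `intensity`.
#' @rdname precondensate-io
#' @export
write_trace_csv <- function(trace, path) {
  check_schema(trace, TRACE_COLS, "trace")
  readr::write_csv(tibble::as_tibble(trace)[, TRACE_COLS], path)
  invisible(path)
}

#' @rdname precondensate-io
#' @export
read_trace_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, TRACE_COLS, "trace")
  df
}

#' @param landscape A `free_energy_landscape` tibble.
#' @rdname precondensate-io
#' @export
write_landscape_table <- function(landscape, path) {
  df <- tibble::as_tibble(landscape)
  if (!"ci_low" %in% names(df)) df$ci_low <- NA_real_
  if (!"ci_high" %in% names(df)) df$ci_high <- NA_real_
  check_schema(df, LANDSCAPE_COLS, "landscape table")
  readr::write_csv(df[, union(LANDSCAPE_COLS, names(df))], path)
  invisible(path)
}

#' @param truth Ground-truth tibble from a `cluster_sim`.
#' @rdname precondensate-io
#' @export
write_truth_csv <- function(truth, path) {
  check_schema(truth, TRUTH_COLS, "ground truth")
  readr::write_csv(truth[, TRUTH_COLS], path)
  invisible(path)
}

#' Write / read a flat key=value configuration file
#'
#' Scalars only; numbers are serialised at full precision (17 significant
#' digits) so a config round-trips losslessly. Unknown keys on read are an
#' error, so typos never pass silently.
#'
#' @param config Named list of scalars (or a `sim_config`).
#' @param path File path.
#' @export
write_config <- function(config, path) {
  flat <- unclass(config)
  flat$landscape <- NULL
  ls <- config$landscape
  if (inherits(ls, "fel_landscape")) {
    flat <- c(list(landscape_preset = ls$preset, landscape_amplitude = ls$amplitude,
                   landscape_exponent = ls$exponent,
                   landscape_plateau_onset = ls$plateau_onset,
                   landscape_wall_size = ls$wall_size,
                   landscape_cap_size = ls$cap_size), flat)
  }
  lines <- vapply(names(flat), function(k) {
    v <- flat[[k]]
    val <- if (is.character(v)) paste(v, collapse = ",") else
      paste(format(v, digits = 17, scientific = FALSE, trim = TRUE), collapse = ",")
    paste0(k, " = ", val)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @param strict Error on keys that [sim_config()] does not know?
#' @rdname write_config
#' @export
read_config <- function(path, strict = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
                     call. = FALSE)
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- lapply(kv, function(x) {
    parts <- strsplit(x[[2]], ",")[[1]]
    if (all(parts %in% c("TRUE", "FALSE"))) return(as.logical(parts))
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  })
  names(vals) <- keys

  known <- c(names(formals(sim_config)),
             paste0("landscape_", c("preset", "amplitude", "exponent",
                                    "plateau_onset", "wall_size", "cap_size")))
  known <- setdiff(known, "landscape")
  unknown <- setdiff(keys, known)
  if (strict && length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  lsp <- vals[startsWith(names(vals), "landscape_")]
  rest <- vals[!startsWith(names(vals), "landscape_")]
  landscape <- free_energy_landscape(
    preset = if (!is.null(lsp$landscape_preset)) lsp$landscape_preset else "stressed",
    amplitude = lsp$landscape_amplitude %||% 0.5,
    exponent = lsp$landscape_exponent %||% (2 / 3),
    plateau_onset = lsp$landscape_plateau_onset %||% 27,
    wall_size = lsp$landscape_wall_size %||% 150,
    cap_size = lsp$landscape_cap_size %||% 600
  )
  do.call(sim_config, c(list(landscape = landscape), rest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
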