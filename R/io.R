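# ---- delimited and TIFF I/O -------------------------------------------------

#' Write a force sweep to a delimited table plus JSON sidecar
#'
#' The table holds `time_s`, `x_trap1_um`, `f1_pN`, `f2_pN`, `freq_hz`;
#' acquisition metadata (sampling rate, drive frequencies, droplet
#' diameter, medium viscosity, seed) goes to `<path>.json`.
#'
#' @param sweep a `force_sweep`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_force_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "force_sweep"))
  utils::write.csv(sweep$data, path, row.names = FALSE)
  meta <- list(
    drive_frequencies = sweep$drive_frequencies,
    sampling_rate = sweep$sampling_rate,
    amplitude_um = sweep$amplitude_um,
    diameter = sweep$diameter,
    medium_viscosity = sweep$medium_viscosity,
    seed = sweep$seed
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a force sweep written by [write_force_sweep()]
#'
#' @param path CSV path; metadata is read from `<path>.json` unless
#'   overridden.
#' @param diameter,medium_viscosity override the sidecar values (um,
#'   Pa s).
#' @return a `force_sweep`.
#' @export
read_force_sweep <- function(path, diameter = NULL, medium_viscosity = NULL) {
  d <- utils::read.csv(path)
  need <- c("time_s", "x_trap1_um", "f1_pN", "f2_pN", "freq_hz")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop("force sweep table ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  fs <- if (!is.null(meta$sampling_rate)) meta$sampling_rate else {
    1 / stats::median(diff(d$time_s))
  }
  out <- list(
    data = d,
    drive_frequencies = sort(unique(d$freq_hz)),
    sampling_rate = fs,
    amplitude_um = meta$amplitude_um,
    diameter = diameter %||% meta$diameter,
    medium_viscosity = medium_viscosity %||% meta$medium_viscosity,
    seed = meta$seed
  )
  class(out) <- "force_sweep"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read/write particle track tables
#'
#' Delimited tables with columns `track_id`, `frame`, `t_s`, `x_um`,
#' `y_um` and optionally `bin`.
#'
#' @param path CSV path.
#' @param tracks data.frame of tracks.
#' @return `read_tracks`: the data.frame; `write_tracks`: `path`.
#' @export
read_tracks <- function(path) {
  d <- utils::read.csv(path)
  need <- c("track_id", "frame", "t_s", "x_um", "y_um")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop("track table ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  d
}

#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' Read/write image stacks as multi-page TIFF
#'
#' TIFF samples are stored in `[0, 1]`; arbitrary intensity units are
#' preserved by rescaling with a single per-stack factor recorded in a
#' `<path>.json` sidecar and re-applied on read.
#'
#' @param images a matrix or list of matrices (pages).
#' @param path TIFF path.
#' @return `read_image_stack`: list of matrices; `write_image_stack`:
#'   `path`.
#' @export
write_image_stack <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  lo <- min(vapply(images, min, numeric(1)))
  hi <- max(vapply(images, max, numeric(1)))
  scale <- max(hi - lo, 1e-12)
  scaled <- lapply(images, function(m) (m - lo) / scale)
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(offset = lo, scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  img <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(img)) img <- list(img)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    img <- lapply(img, function(m) m * meta$scale + meta$offset)
  }
  img
}

#' Read a pressure-displacement calibration table
#'
#' @param path CSV with columns `pressure_kPa`, `displacement_um`.
#' @return data.frame.
#' @export
read_calibration_table <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("pressure_kPa", "displacement_um") %in% names(d))) {
    stop("calibration table ", path,
         " needs columns pressure_kPa, displacement_um")
  }
  d
}
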