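#' Write a time-lapse stack as multi-page TIFF
#'
#' Pages are ordered TZYX (hyperstack convention: all z-planes of frame 1,
#' then frame 2, ...). TIFF samples are stored normalized to `[0, 1]`; the
#' intensity scale and the physical calibration (pixel size, frame interval,
#' z-step, shape) travel in a sidecar JSON file at `<path>.json`, since the
#' TIFF writer cannot embed arbitrary tags.
#'
#' @param stack A [timelapse_stack()].
#' @param path Output TIFF path.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$data)
  mx <- max(stack$data)
  scale <- if (mx > 0) mx else 1
  pages <- vector("list", d[1] * d[2])
  i <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    i <- i + 1L
    pages[[i]] <- stack$data[t, z, , ] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(axes = "TZYX", n_frames = d[1], n_z = d[2], ny = d[3], nx = d[4],
         pixel_size_um = stack$pixel_size_um,
         frame_interval_s = stack$frame_interval_s,
         z_step_um = stack$z_step_um, intensity_scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a time-lapse stack written by [write_stack()]
#'
#' @param path TIFF path; the sidecar `<path>.json` must be present.
#' @return A [timelapse_stack()].
#' @export
read_stack <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop(sprintf("missing calibration sidecar '%s'", meta_path),
         call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(meta$n_frames, meta$n_z, meta$ny, meta$nx)
  if (length(pages) != d[1] * d[2])
    stop("page count does not match sidecar shape", call. = FALSE)
  data <- array(0, dim = d)
  i <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    i <- i + 1L
    data[t, z, , ] <- pages[[i]] * meta$intensity_scale
  }
  timelapse_stack(data, meta$pixel_size_um, meta$frame_interval_s,
                  meta$z_step_um)
}

#' Write a projected series as multi-page TIFF (TYX) with provenance sidecar
#'
#' @param series A [projected_series()].
#' @param path Output TIFF path; provenance and calibration go to
#'   `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "projected_series"))
  d <- dim(series$data)
  mx <- max(series$data)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(d[1]), function(t) series$data[t, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  prov <- lapply(series$provenance, function(p)
    lapply(p, function(v) if (is.matrix(v)) apply(v, 1, as.numeric,
                                                  simplify = FALSE) else v))
  jsonlite::write_json(
    list(axes = "TYX", n_frames = d[1], ny = d[2], nx = d[3],
         pixel_size_um = series$pixel_size_um,
         frame_interval_s = series$frame_interval_s,
         binary = series$binary, intensity_scale = scale,
         provenance = prov),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write detected events and stability results as CSV
#'
#' @param ev A classified [detect_extensions()] result.
#' @param results A [stability_index()] data frame.
#' @param events_path,results_path Output CSV paths.
#' @return Invisibly, the paths written.
#' @export
write_motility_csv <- function(ev, results, events_path, results_path) {
  stopifnot(inherits(ev, "extension_events"))
  write.csv(ev$events, events_path, row.names = FALSE)
  write.csv(results, results_path, row.names = FALSE)
  invisible(c(events_path, results_path))
}
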