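#' Build a minimal binary toy series with scripted extension events
#'
#' The oracle substrate for the motility stage: a binary series where a fixed
#' base mask is present in every frame and each scripted event's pixel block
#' is present exactly during `[onset, onset + lifetime - 1]`. Because every
#' event's footprint and lifetime are scripted, the stability index of the
#' series is known by enumeration.
#'
#' @param event_spec List of events, each a list with `onset_frame` (>= 2: an
#'   extension needs a preceding frame to be "new"), `pixels` (linear indices
#'   into the `(ny, nx)` frame, or a 2-column `(y, x)` matrix), and
#'   `lifetime_frames` (>= 1).
#' @param n_frames Number of frames.
#' @param base_mask Logical `(ny, nx)` matrix present in all frames; event
#'   blocks must not overlap it.
#' @param pixel_size_um,frame_interval_s Calibration metadata.
#' @return A binary [projected_series()] with attribute `"event_spec"`.
#' @export
make_toy_binary_series <- function(event_spec, n_frames, base_mask,
                                   pixel_size_um = 0.273,
                                   frame_interval_s = 60) {
  stopifnot(is.matrix(base_mask))
  check_count(n_frames, "n_frames", min = 1L)
  ny <- nrow(base_mask); nx <- ncol(base_mask)
  norm_px <- function(p) {
    if (is.matrix(p)) p <- (p[, 2] - 1L) * ny + p[, 1]
    as.integer(p)
  }
  events <- lapply(event_spec, function(ev) {
    check_count(ev$onset_frame, "onset_frame", min = 2L)
    check_count(ev$lifetime_frames, "lifetime_frames", min = 1L)
    px <- norm_px(ev$pixels)
    if (any(px < 1L | px > ny * nx))
      stop("event pixels outside the image", call. = FALSE)
    if (any(base_mask[px]))
      stop("event block overlaps base_mask", call. = FALSE)
    list(onset_frame = as.integer(ev$onset_frame), pixels = px,
         lifetime_frames = as.integer(ev$lifetime_frames))
  })
  data <- array(FALSE, dim = c(n_frames, ny, nx))
  for (t in seq_len(n_frames)) {
    m <- base_mask
    for (ev in events) {
      if (t >= ev$onset_frame && t <= ev$onset_frame + ev$lifetime_frames - 1L)
        m[ev$pixels] <- TRUE
    }
    data[t, , ] <- m
  }
  out <- projected_series(data * 1.0, pixel_size_um, frame_interval_s,
                          provenance = list(list(step = "correct_drift",
                                                 shifts = matrix(0, n_frames, 2),
                                                 synthetic = TRUE)),
                          binary = TRUE)
  attr(out, "event_spec") <- events
  out
}
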