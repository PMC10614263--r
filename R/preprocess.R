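#' Maximum-intensity z-projection
#'
#' Collapses a 4D stack to a 2D+time series by taking, at every `(frame, y,
#' x)`, the maximum over the selected z-planes. Calibration metadata is
#' propagated unchanged.
#'
#' @param stack A [timelapse_stack()].
#' @param z_range Optional length-2 numeric: slab to project, in micrometres
#'   from the first plane (plane `z` sits at `(z - 1) * z_step_um`). `NULL`
#'   projects the full depth.
#' @return A [projected_series()].
#' @export
max_project <- function(stack, z_range = NULL) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$data)
  nz <- d[2]
  z_pos <- (seq_len(nz) - 1) * stack$z_step_um
  planes <- if (is.null(z_range)) seq_len(nz) else {
    if (length(z_range) != 2L || z_range[2] < z_range[1])
      stop("`z_range` must be c(lo, hi) in micrometres", call. = FALSE)
    which(z_pos >= z_range[1] & z_pos <= z_range[2])
  }
  if (length(planes) == 0L)
    stop("empty z slab: no planes within `z_range`", call. = FALSE)
  out <- array(0, dim = d[c(1, 3, 4)])
  for (t in seq_len(d[1])) {
    acc <- stack$data[t, planes[1], , ]
    for (z in planes[-1]) acc <- pmax(acc, stack$data[t, z, , ])
    out[t, , ] <- acc
  }
  projected_series(out, stack$pixel_size_um, stack$frame_interval_s,
                   provenance = list(list(step = "max_project",
                                          planes = planes)))
}

# integer-pixel translation offset of `moved` relative to `ref` by
# phase correlation; returns c(dy, dx) such that
# moved ~= translate_int(ref, dy, dx)
phase_shift <- function(ref, moved) {
  if (sd(ref) < 1e-12 || sd(moved) < 1e-12) {
    warning("degenerate (constant) frame; shift set to (0, 0)")
    return(c(0L, 0L))
  }
  A <- stats::fft(ref)
  B <- stats::fft(moved)
  R <- B * Conj(A)
  R <- R / pmax(Mod(R), 1e-12)
  r <- Re(stats::fft(R, inverse = TRUE))
  pk <- which.max(r)
  ny <- nrow(ref); nx <- ncol(ref)
  dy <- (pk - 1L) %% ny
  dx <- (pk - 1L) %/% ny
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  c(dy, dx)
}

#' Correct translational stage drift
#'
#' Registers every frame to the first frame by integer-pixel translation
#' estimated with phase correlation. Integer shifts (no interpolation) keep
#' the analysis pixel-presence-exact; registering all frames to frame 1
#' rather than pairwise prevents accumulation of estimation error. Estimated
#' shifts are recorded in the provenance (one `(dy, dx)` row per frame; frame
#' 1 is `(0, 0)`).
#'
#' @param series A [projected_series()] with at least 2 frames.
#' @param fill Value for pixels vacated by the correction (default: the
#'   median of the first frame, an estimate of background).
#' @return The registered [projected_series()].
#' @export
correct_drift <- function(series, fill = NULL) {
  stopifnot(inherits(series, "projected_series"))
  Tn <- n_frames(series)
  if (Tn < 2L) stop("drift correction needs at least 2 frames", call. = FALSE)
  ref <- get_frame(series, 1L)
  if (is.null(fill)) fill <- median(ref)
  shifts <- matrix(0L, Tn, 2L, dimnames = list(NULL, c("dy", "dx")))
  out <- series$data
  for (t in 2:Tn) {
    fr <- get_frame(series, t)
    s <- phase_shift(ref, fr)
    shifts[t, ] <- s
    if (any(s != 0L)) out[t, , ] <- translate_int(fr, -s[1], -s[2], fill = fill)
  }
  series$data <- out
  add_provenance(series, list(step = "correct_drift", shifts = shifts))
}

#' Correct photobleaching by frame-mean normalization
#'
#' Rescales frame `t` by `mean(frame 1) / mean(frame t)` so that the mean
#' intensity is constant across frames. Correction factors are recorded in
#' provenance (frame 1 has factor 1).
#'
#' @param series An intensity [projected_series()].
#' @return The bleach-corrected [projected_series()].
#' @export
correct_bleach <- function(series) {
  stopifnot(inherits(series, "projected_series"))
  Tn <- n_frames(series)
  means <- vapply(seq_len(Tn), function(t) mean(get_frame(series, t)),
                  numeric(1))
  if (any(means <= 0))
    stop(sprintf("frame %d has non-positive mean intensity; cannot normalize",
                 which(means <= 0)[1]), call. = FALSE)
  factors <- means[1] / means
  out <- series$data
  for (t in seq_len(Tn)) if (factors[t] != 1) out[t, , ] <- out[t, , ] * factors[t]
  series$data <- out
  add_provenance(series, list(step = "correct_bleach", factors = factors))
}

#' Threshold an intensity series to binary
#'
#' A single threshold -- Otsu's method computed on the first frame, or a
#' user-fixed value -- is applied to every frame. Using one global threshold
#' (rather than per-frame thresholds) is essential for motility scoring:
#' per-frame threshold jitter would create spurious extension and retraction
#' events.
#'
#' @param series An intensity [projected_series()].
#' @param method `"otsu"` (threshold from Otsu's method on frame 1) or
#'   `"fixed"`.
#' @param threshold Numeric threshold, required for `method = "fixed"`.
#' @return A binary [projected_series()]; the threshold used is recorded in
#'   provenance.
#' @export
binarize <- function(series, method = c("otsu", "fixed"), threshold = NULL) {
  stopifnot(inherits(series, "projected_series"))
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(threshold))
      stop("`threshold` is required when method = \"fixed\"", call. = FALSE)
    thr <- threshold
  } else {
    f1 <- get_frame(series, 1L)
    mx <- max(f1)
    if (mx <= 0) {
      warning("all-zero first frame; binarized series is all background")
      thr <- Inf
    } else {
      thr <- EBImage::otsu(EBImage::Image(f1 / mx), range = c(0, 1)) * mx
    }
  }
  series$data <- (series$data > thr) * 1.0
  series$binary <- TRUE
  add_provenance(series, list(step = "binarize", method = method,
                              threshold = thr))
}
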