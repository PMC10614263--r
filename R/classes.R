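#' @importFrom stats sd rbinom rpois runif rnorm aov TukeyHSD t.test pf median
#' @importFrom utils write.csv read.csv packageVersion modifyList
NULL

#' Construct a calibrated 4D time-lapse stack
#'
#' The raw container every analysis starts from: a `(frame, z, y, x)` intensity
#' array together with the physical calibration (pixel size, frame interval,
#' z-step) from which every micrometre-scale number downstream derives.
#'
#' @param data 4D numeric array, dimensions `(n_frames, n_z, ny, nx)`.
#' @param pixel_size_um Lateral pixel size in micrometres per pixel.
#' @param frame_interval_s Time between consecutive frames, seconds.
#' @param z_step_um Axial spacing between z-planes, micrometres.
#' @return An object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(data, pixel_size_um, frame_interval_s, z_step_um = 1) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (frame, z, y, x)", call. = FALSE)
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  check_positive_scalar(frame_interval_s, "frame_interval_s")
  check_positive_scalar(z_step_um, "z_step_um")
  structure(
    list(data = data, pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s, z_step_um = z_step_um),
    class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<timelapse_stack> %d frames x %d z x %d x %d px | %.3f um/px, %g s/frame, %g um/z\n",
    d[1], d[2], d[3], d[4], x$pixel_size_um, x$frame_interval_s, x$z_step_um))
  invisible(x)
}

#' @export
dim.timelapse_stack <- function(x) dim(x$data)

#' Construct a projected 2D+time series
#'
#' The substrate of all scoring: a `(frame, y, x)` array (intensity or binary)
#' with calibration metadata and an ordered provenance record of every
#' correction applied to it (estimated drift shifts, bleach factors,
#' binarization threshold).
#'
#' @param data 3D numeric or logical array, dimensions `(n_frames, ny, nx)`.
#' @param pixel_size_um Micrometres per pixel.
#' @param frame_interval_s Seconds between frames.
#' @param provenance List of named correction records, in application order.
#' @param binary Logical; `TRUE` once the series has been thresholded.
#' @return An object of class `projected_series`.
#' @export
projected_series <- function(data, pixel_size_um, frame_interval_s,
                             provenance = list(), binary = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (frame, y, x)", call. = FALSE)
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  check_positive_scalar(frame_interval_s, "frame_interval_s")
  structure(
    list(data = data, pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s,
         provenance = provenance, binary = isTRUE(binary)),
    class = "projected_series")
}

#' @export
print.projected_series <- function(x, ...) {
  d <- dim(x$data)
  steps <- if (length(x$provenance)) paste(vapply(x$provenance, `[[`, "", "step"),
                                           collapse = " -> ") else "none"
  cat(sprintf("<projected_series%s> %d frames x %d x %d px | %.3f um/px | steps: %s\n",
              if (x$binary) " (binary)" else "", d[1], d[2], d[3],
              x$pixel_size_um, steps))
  invisible(x)
}

#' @export
dim.projected_series <- function(x) dim(x$data)

# one frame as a (y, x) matrix
get_frame <- function(series, t) {
  series$data[t, , , drop = TRUE]
}

n_frames <- function(x) dim(x$data)[1]

has_provenance_step <- function(series, step) {
  any(vapply(series$provenance, function(p) identical(p$step, step), logical(1)))
}

add_provenance <- function(series, record) {
  series$provenance <- c(series$provenance, list(record))
  series
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  invisible(TRUE)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  invisible(TRUE)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  invisible(TRUE)
}

# odd-sized disc brush for a radius given in pixels (radius 0 -> 1x1)
disc_brush <- function(radius_px) {
  size <- 2L * as.integer(floor(radius_px)) + 1L
  if (size < 3L) return(matrix(1, 1, 1))
  EBImage::makeBrush(size, shape = "disc")
}

box3 <- function() matrix(1, 3, 3)

# 8-connected component labeling (EBImage::bwlabel is 4-connected; process
# extensions are thin and often diagonally connected, so events must be
# grouped with 8-connectivity). BFS over the foreground pixel set.
label8 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  todo <- which(mask)
  if (length(todo) == 0L) return(lab)
  nbr_off <- c(-1L, 1L, -ny, ny, -ny - 1L, -ny + 1L, ny - 1L, ny + 1L)
  cur <- 0L
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      py <- ((p - 1L) %% ny) + 1L
      for (o in nbr_off) {
        q <- p + o
        if (q < 1L || q > ny * nx) next
        qy <- ((q - 1L) %% ny) + 1L
        if (abs(qy - py) > 1L) next          # column wrap guard
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# is a pixel-index set one 8-connected component?
is_connected8 <- function(idx, ny, nx) {
  if (length(idx) <= 1L) return(TRUE)
  m <- matrix(FALSE, ny, nx)
  m[idx] <- TRUE
  max(label8(m)) == 1L
}

# integer-shift a matrix by (dy, dx), filling vacated pixels with `fill`
translate_int <- function(m, dy, dx, fill = 0) {
  dy <- as.integer(round(dy)); dx <- as.integer(round(dx))
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- seq_len(ny); xs <- seq_len(nx)
  ysrc <- ys - dy; xsrc <- xs - dx
  yok <- ysrc >= 1L & ysrc <= ny
  xok <- xsrc >= 1L & xsrc <= nx
  if (any(yok) && any(xok))
    out[ys[yok], xs[xok]] <- m[ysrc[yok], xsrc[xok]]
  out
}
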