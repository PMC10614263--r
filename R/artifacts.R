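#' Apply acquisition artifacts to a clean stack
#'
#' Corrupts a rendered stack with the three defects the preprocessing stage
#' must undo: cumulative stage drift (frame `t` translated by
#' `(t-1) * drift`, integer pixels), exponential photobleaching (intensities
#' multiplied by `exp(-bleach_rate * (t-1))`), and Poisson shot noise.
#' With `drift = c(0, 0)`, `bleach_rate = 0` and `noise_scale = 0` the stack
#' is returned unchanged, exactly.
#'
#' @param stack A [timelapse_stack()].
#' @param drift Length-2 numeric `(dy, dx)`: stage drift per frame, pixels.
#' @param bleach_rate Per-frame exponential decay constant (>= 0).
#' @param noise_scale Shot-noise scale; photon counts are drawn as
#'   `rpois(intensity / noise_scale) * noise_scale`. 0 disables noise.
#' @param fill Intensity used for pixels drifting into the field (background
#'   level, so drift does not create spurious dark borders).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (the simulator calls this inside its own seeded stream).
#' @return A [timelapse_stack()] of identical shape.
#' @export
apply_artifacts <- function(stack, drift = c(0, 0), bleach_rate = 0,
                            noise_scale = 0, fill = 0, seed = NULL) {
  stopifnot(inherits(stack, "timelapse_stack"))
  if (length(drift) != 2L || any(!is.finite(drift)))
    stop("`drift` must be a finite length-2 (dy, dx) vector", call. = FALSE)
  if (bleach_rate < 0) stop("`bleach_rate` must be >= 0", call. = FALSE)
  if (noise_scale < 0) stop("`noise_scale` must be >= 0", call. = FALSE)
  run <- function() {
    d <- dim(stack$data)
    Tn <- d[1]; nz <- d[2]
    out <- stack$data
    for (t in seq_len(Tn)) {
      dy <- round((t - 1) * drift[1]); dx <- round((t - 1) * drift[2])
      fac <- exp(-bleach_rate * (t - 1))
      for (z in seq_len(nz)) {
        fr <- out[t, z, , ]
        if (dy != 0 || dx != 0) fr <- translate_int(fr, dy, dx, fill = fill)
        if (bleach_rate > 0) fr <- fr * fac
        if (noise_scale > 0)
          fr <- matrix(rpois(length(fr), pmax(fr, 0) / noise_scale),
                       nrow(fr), ncol(fr)) * noise_scale
        out[t, z, , ] <- fr
      }
    }
    stack$data <- out
    stack
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
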