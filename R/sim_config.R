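#' Simulation configuration for synthetic microglia time-lapse stacks
#'
#' Defaults emulate confocal live imaging of lectin-labeled microglia in acute
#' brain slices: a 512 x 512 px field covering ~140 um (0.273 um/px), one
#' frame per minute for 10 min, z-stacks at 2 um spacing over ~30 um.
#' Cell geometry is a disk soma with piecewise-linear branched processes;
#' extensions are new terminal segments appearing at process tips.
#'
#' @param image_size Pixels per side of the (square) field of view.
#' @param pixel_size_um Micrometres per pixel.
#' @param n_frames Number of time points (>= 3; the 3-frame persistence
#'   window is undefined below that).
#' @param frame_interval_s Seconds between frames.
#' @param n_z Number of z-planes.
#' @param z_step_um Axial plane spacing, micrometres.
#' @param n_cells Number of microglia in the field.
#' @param soma_radius_um Soma radius, micrometres.
#' @param n_primary_processes Primary processes per cell.
#' @param process_length_um Total polyline length of each primary process.
#' @param process_width_um Rendered process thickness.
#' @param branch_prob Probability a primary process carries one side branch.
#' @param extension_prob Per-tip, per-frame probability that a new terminal
#'   extension appears.
#' @param stable_fraction Probability a new extension is persistent (remains
#'   from onset through the final frame).
#' @param unstable_lifetime_frames Lifetime (frames) of non-persistent
#'   extensions.
#' @param extension_length_um Length of one extension segment.
#' @param cup_fraction Fraction of cells rendered with a phagocytic cup (an
#'   open annulus at one process terminal).
#' @param cup_radius_um Outer radius of the rendered cup.
#' @param psf_sigma_um Gaussian point-spread-function sigma (lateral).
#' @param background Background intensity level (cell amplitude is 1).
#' @param noise_scale Shot-noise scale: photon counts are drawn as
#'   `rpois(intensity / noise_scale) * noise_scale`; 0 disables noise.
#' @param bleach_rate Per-frame exponential intensity decay constant.
#' @param drift_px_per_frame Length-2 numeric `(dy, dx)` stage drift per frame
#'   in pixels.
#' @param seed Integer seed; identical seed + config give bit-identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(image_size = 512L,
                       pixel_size_um = 0.273,
                       n_frames = 10L,
                       frame_interval_s = 60,
                       n_z = 15L,
                       z_step_um = 2,
                       n_cells = 4L,
                       soma_radius_um = 4,
                       n_primary_processes = 5L,
                       process_length_um = 12,
                       process_width_um = 0.8,
                       branch_prob = 0.3,
                       extension_prob = 0.35,
                       stable_fraction = 0.5,
                       unstable_lifetime_frames = 1L,
                       extension_length_um = 3,
                       cup_fraction = 0,
                       cup_radius_um = 1.6,
                       psf_sigma_um = 0.3,
                       background = 0.02,
                       noise_scale = 0.01,
                       bleach_rate = 0.05,
                       drift_px_per_frame = c(0, 0),
                       seed = 1L) {
  cfg <- list(
    image_size = as.integer(image_size), pixel_size_um = pixel_size_um,
    n_frames = as.integer(n_frames), frame_interval_s = frame_interval_s,
    n_z = as.integer(n_z), z_step_um = z_step_um,
    n_cells = as.integer(n_cells), soma_radius_um = soma_radius_um,
    n_primary_processes = as.integer(n_primary_processes),
    process_length_um = process_length_um,
    process_width_um = process_width_um, branch_prob = branch_prob,
    extension_prob = extension_prob, stable_fraction = stable_fraction,
    unstable_lifetime_frames = as.integer(unstable_lifetime_frames),
    extension_length_um = extension_length_um,
    cup_fraction = cup_fraction, cup_radius_um = cup_radius_um,
    psf_sigma_um = psf_sigma_um, background = background,
    noise_scale = noise_scale, bleach_rate = bleach_rate,
    drift_px_per_frame = as.numeric(drift_px_per_frame),
    seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_count(cfg$image_size, "image_size", min = 16L)
  check_positive_scalar(cfg$pixel_size_um, "pixel_size_um")
  check_count(cfg$n_frames, "n_frames", min = 3L)
  check_positive_scalar(cfg$frame_interval_s, "frame_interval_s")
  check_count(cfg$n_z, "n_z", min = 1L)
  check_positive_scalar(cfg$z_step_um, "z_step_um")
  check_count(cfg$n_cells, "n_cells", min = 0L)
  check_positive_scalar(cfg$soma_radius_um, "soma_radius_um")
  check_count(cfg$n_primary_processes, "n_primary_processes", min = 1L)
  check_positive_scalar(cfg$process_length_um, "process_length_um")
  check_positive_scalar(cfg$process_width_um, "process_width_um")
  for (p in c("branch_prob", "extension_prob", "stable_fraction",
              "cup_fraction"))
    check_probability(cfg[[p]], p)
  check_count(cfg$unstable_lifetime_frames, "unstable_lifetime_frames",
              min = 1L)
  check_positive_scalar(cfg$extension_length_um, "extension_length_um")
  check_positive_scalar(cfg$cup_radius_um, "cup_radius_um")
  check_positive_scalar(cfg$psf_sigma_um, "psf_sigma_um")
  if (!is.numeric(cfg$background) || cfg$background < 0)
    stop("`background` must be >= 0", call. = FALSE)
  if (!is.numeric(cfg$noise_scale) || cfg$noise_scale < 0)
    stop("`noise_scale` must be >= 0", call. = FALSE)
  if (!is.numeric(cfg$bleach_rate) || cfg$bleach_rate < 0)
    stop("`bleach_rate` must be >= 0", call. = FALSE)
  if (length(cfg$drift_px_per_frame) != 2L ||
      any(!is.finite(cfg$drift_px_per_frame)))
    stop("`drift_px_per_frame` must be a finite length-2 (dy, dx) vector",
         call. = FALSE)
  check_count(cfg$seed, "seed")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %d px (%.3f um/px), %d frames @ %gs, %d z @ %g um | ",
           "%d cells, ext p=%.2f, stable=%.2f, seed=%d\n"),
    x$image_size, x$pixel_size_um, x$n_frames, x$frame_interval_s, x$n_z,
    x$z_step_um, x$n_cells, x$extension_prob, x$stable_fraction, x$seed))
  invisible(x)
}
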