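# shared fixtures: all built in code at test time

# stack a list of (y, x) matrices into a (frame, y, x) series array
frames_to_array <- function(frames) {
  ny <- nrow(frames[[1]]); nx <- ncol(frames[[1]])
  out <- array(0, c(length(frames), ny, nx))
  for (t in seq_along(frames)) out[t, , ] <- frames[[t]]
  out
}

# wrap a single binary mask as a 1-frame binary series
mask_series <- function(mask, pixel_size_um = 0.273) {
  projected_series(array(mask * 1.0, dim = c(1, nrow(mask), ncol(mask))),
                   pixel_size_um, 60, binary = TRUE)
}

disk_mask <- function(r, n = 2 * r + 21, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  yy <- row(matrix(0, n, n)); xx <- col(matrix(0, n, n))
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

plus_mask <- function(n = 60, arm_half = 20, w = 1) {
  m <- matrix(FALSE, n, n)
  c0 <- n %/% 2
  m[(c0 - w):(c0 + w), (c0 - arm_half):(c0 + arm_half)] <- TRUE
  m[(c0 - arm_half):(c0 + arm_half), (c0 - w):(c0 + w)] <- TRUE
  m
}

# soma disk + straight process ending in a ring (cup) with known cavity
cup_cell_mask <- function(gap = FALSE) {
  m <- matrix(FALSE, 120, 120)
  yy <- row(m); xx <- col(m)
  m[(yy - 60)^2 + (xx - 30)^2 <= 15^2] <- TRUE
  m[59:61, 30:85] <- TRUE
  ring <- (yy - 60)^2 + (xx - 92)^2
  wall <- ring <= 7^2 & ring >= 5^2
  if (gap) {
    # mouth faces +y, away from the process entry at angle pi
    ang <- atan2(yy - 60, xx - 92)
    wall <- wall & !(abs(ang - pi / 2) < 0.45)
  }
  m[wall] <- TRUE
  list(mask = m, cavity_px = sum(ring < 5^2))
}

# one random toy series plus its brute-force enumerated stability index:
# 3x3 blocks on distinct sites touching a base bar; the oracle scores each
# scripted (block, lifetime) pair against the >= 3-frame rule directly
random_toy_case <- function() {
  ny <- 60; nx <- 120
  n_frames <- sample(6:12, 1)
  base <- matrix(FALSE, ny, nx)
  base[30:32, 5:115] <- TRUE
  sites <- seq(8, 112, by = 5)
  cols <- sample(sites, sample(3:12, 1))
  spec <- lapply(cols, function(cc) list(
    onset_frame = sample(2:n_frames, 1),
    pixels = as.matrix(expand.grid(y = 27:29, x = (cc - 1):(cc + 1))),
    lifetime_frames = sample(1:n_frames, 1)))
  eff <- vapply(spec, function(e)
    min(e$lifetime_frames, n_frames - e$onset_frame + 1), numeric(1))
  list(series = make_toy_binary_series(spec, n_frames, base),
       n_events = length(spec),
       oracle_si = mean(eff >= 3))
}

# pipeline stability index (pooled) of a binary series
pipeline_si <- function(series, min_event_px = 1L, threshold_frames = 3L) {
  seg <- segment_cells(series, min_area_px = 20)
  ev <- detect_extensions(series, seg, min_event_px = min_event_px)
  ev <- classify_stability(ev, series,
                           stability_threshold_frames = threshold_frames)
  stability_index(ev, per_cell = FALSE)
}

# compact simulation configs used across tests (field ~105 um, 5 z-planes;
# enough tips to generate tens of events in 10 frames)
test_sim_config <- function(...) {
  defaults <- list(image_size = 384L, n_z = 5L, n_cells = 4L,
                   n_primary_processes = 6L, extension_prob = 0.4,
                   noise_scale = 0, bleach_rate = 0,
                   drift_px_per_frame = c(0, 0))
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# full preprocessing chain on a raw stack
preprocess_chain <- function(stack) {
  binarize(correct_bleach(correct_drift(max_project(stack))))
}
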