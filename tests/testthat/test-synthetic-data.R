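test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(pixel_size_um = -1), "pixel_size_um")
  expect_error(sim_config(extension_prob = 1.5), "extension_prob")
  expect_error(sim_config(n_frames = 2), "n_frames")
  expect_error(sim_config(drift_px_per_frame = 1), "drift_px_per_frame")
})

test_that("simulation is deterministic under seed and has the declared shape", {
  cfg <- test_sim_config(image_size = 128L, n_cells = 1L, n_z = 3L, seed = 9L,
                         noise_scale = 0.01)
  a <- simulate_timelapse(cfg)
  b <- simulate_timelapse(cfg)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$events, b$truth$events)
  expect_equal(dim(a$stack$data), c(10L, 3L, 128L, 128L))
  expect_equal(nrow(a$truth$drift), 10L)
  expect_length(a$truth$bleach, 10L)
})

test_that("no-cell and no-event degenerate cases are flagged", {
  empty <- simulate_timelapse(test_sim_config(image_size = 64L, n_cells = 0L,
                                              n_z = 2L, seed = 1L))
  expect_equal(nrow(empty$truth$cells), 0L)
  expect_equal(nrow(empty$truth$events), 0L)
  expect_true(empty$truth$stability_index$undefined)

  still <- simulate_timelapse(test_sim_config(image_size = 192L, n_cells = 1L,
                                              extension_prob = 0, seed = 2L))
  expect_equal(nrow(still$truth$events), 0L)
  expect_true(still$truth$stability_index$undefined)
})

test_that("every ground-truth event footprint is present at its onset frame", {
  sim <- simulate_timelapse(test_sim_config(seed = 4L))
  ev <- sim$truth$events
  expect_gt(nrow(ev), 20)
  for (i in seq_len(nrow(ev))) {
    fr <- sim$truth$geometry[ev$onset_frame[i], , ]
    foot <- sim$truth$event_footprints[[i]]
    expect_true(all(fr[foot]))
    prev <- sim$truth$geometry[ev$onset_frame[i] - 1L, , ]
    expect_false(any(prev[foot]))
  }
})

test_that("realized stable fraction matches the nominal probability", {
  # pool several seeds for a large event count, then check against the
  # binomial 99.7% band around p = 0.8
  stable <- integer(0)
  for (s in 1:3) {
    sim <- simulate_timelapse(test_sim_config(stable_fraction = 0.8,
                                              seed = 100L + s))
    stable <- c(stable, sim$truth$events$stable)
  }
  n <- length(stable)
  expect_gte(n, 50)
  band <- 3 * sqrt(0.8 * 0.2 / n)
  expect_lt(abs(mean(stable) - 0.8), band + 1e-12)
})

test_that("toy series places blocks exactly during their lifetime", {
  base <- matrix(FALSE, 20, 20); base[10:12, 2:18] <- TRUE
  blk <- as.matrix(expand.grid(y = 7:9, x = 8:10))
  series <- make_toy_binary_series(
    list(list(onset_frame = 3, pixels = blk, lifetime_frames = 5)),
    n_frames = 10, base_mask = base)
  on_px <- (blk[, 2] - 1) * 20 + blk[, 1]
  for (t in 1:10) {
    fr <- series$data[t, , ] > 0
    expect_equal(all(fr[on_px]), t >= 3 && t <= 7, info = paste("frame", t))
    expect_true(all(fr[base]))
  }
  # empty spec: every frame equals the base mask
  s2 <- make_toy_binary_series(list(), 4, base)
  for (t in 1:4) expect_equal(s2$data[t, , ] > 0, base)
})

test_that("toy series rejects blocks overlapping the base mask", {
  base <- matrix(FALSE, 20, 20); base[10:12, 2:18] <- TRUE
  bad <- as.matrix(expand.grid(y = 10:12, x = 8:10))
  expect_error(make_toy_binary_series(
    list(list(onset_frame = 2, pixels = bad, lifetime_frames = 1)),
    10, base), "overlaps")
  expect_error(make_toy_binary_series(
    list(list(onset_frame = 1, pixels = cbind(1, 1), lifetime_frames = 1)),
    10, base), "onset_frame")
})

test_that("artifacts: identity, pure drift, and closed-form bleaching", {
  st <- timelapse_stack(array(runif(4 * 2 * 24 * 24), c(4, 2, 24, 24)),
                        0.273, 60, 2)
  expect_identical(apply_artifacts(st)$data, st$data)

  # drift (1, 0): frame 3 is frame 1 shifted 2 px in y
  geom <- array(0, c(3, 1, 30, 30))
  for (t in 1:3) geom[t, 1, 10:14, 10:14] <- 1
  st2 <- apply_artifacts(timelapse_stack(geom, 0.273, 60, 2),
                         drift = c(1, 0))
  expect_equal(st2$data[3, 1, 3:28, ], geom[1, 1, 1:26, ])

  # uniform stack, bleach 0.1: frame-mean ratio frame4/frame1 = exp(-0.3)
  st3 <- apply_artifacts(timelapse_stack(array(0.5, c(5, 2, 16, 16)),
                                         0.273, 60, 2), bleach_rate = 0.1)
  expect_equal(mean(st3$data[4, , , ]) / mean(st3$data[1, , , ]),
               exp(-0.3), tolerance = 1e-12)
})

test_that("event bookkeeping: rendered protrusions match truth 1:1 on clean geometry", {
  sim <- simulate_timelapse(test_sim_config(seed = 7L, stable_fraction = 0.5))
  series <- truth_geometry_series(sim$truth)
  seg <- segment_cells(series)
  ev <- detect_extensions(series, seg, min_event_px = 1L)
  expect_equal(nrow(ev$events), nrow(sim$truth$events))
})
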