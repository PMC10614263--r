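test_that("max projection equals a brute-force loop oracle", {
  set.seed(31)
  data <- array(runif(3 * 4 * 12 * 12), c(3, 4, 12, 12))
  st <- timelapse_stack(data, 0.5, 30, 1.5)
  proj <- max_project(st)
  oracle <- array(0, c(3, 12, 12))
  for (t in 1:3) for (y in 1:12) for (x in 1:12)
    oracle[t, y, x] <- max(data[t, , y, x])
  expect_equal(proj$data, oracle)
  expect_equal(proj$pixel_size_um, 0.5)
  expect_equal(proj$frame_interval_s, 30)
})

test_that("projection over a one-plane slab is the plane itself", {
  set.seed(32)
  data <- array(runif(2 * 5 * 8 * 8), c(2, 5, 8, 8))
  st <- timelapse_stack(data, 0.273, 60, 2)
  proj <- max_project(st, z_range = c(4, 4))        # plane 3 sits at 4 um
  expect_equal(proj$data[1, , ], data[1, 3, , ])
  expect_error(max_project(st, z_range = c(100, 200)), "empty z slab")
})

test_that("known integer drift is recovered exactly and inverted", {
  cfg <- test_sim_config(image_size = 256L, n_z = 3L, n_cells = 2L,
                         n_frames = 5L, seed = 2L,
                         drift_px_per_frame = c(3, -2))
  sim <- simulate_timelapse(cfg)
  reg <- correct_drift(max_project(sim$stack))
  shifts <- reg$provenance[[2]]$shifts
  expect_equal(unname(shifts),
               unname(outer(0:4, c(3, -2))))
  # corrected series matches the drift-free render away from the border
  cfg0 <- test_sim_config(image_size = 256L, n_z = 3L, n_cells = 2L,
                          n_frames = 5L, seed = 2L,
                          drift_px_per_frame = c(0, 0))
  ref <- max_project(simulate_timelapse(cfg0)$stack)
  margin <- 20
  expect_equal(reg$data[5, margin:(256 - margin), margin:(256 - margin)],
               ref$data[5, margin:(256 - margin), margin:(256 - margin)],
               tolerance = 1e-10)
})

test_that("identical frames register with zero shift; constant frames warn", {
  set.seed(33)
  fr <- matrix(runif(64 * 64), 64, 64)
  series <- projected_series(frames_to_array(list(fr, fr, fr)), 0.273, 60)
  reg <- correct_drift(series)
  expect_true(all(reg$provenance[[1]]$shifts == 0))
  flat <- projected_series(array(1, c(2, 16, 16)), 0.273, 60)
  expect_warning(correct_drift(flat), "degenerate")
})

test_that("bleach correction recovers the closed-form factor and flattens means", {
  st <- apply_artifacts(timelapse_stack(array(0.5, c(5, 2, 16, 16)),
                                        0.273, 60, 2), bleach_rate = 0.1)
  fixed <- correct_bleach(max_project(st))
  factors <- fixed$provenance[[2]]$factors
  expect_equal(factors[1], 1)
  expect_equal(factors[4], exp(0.3), tolerance = 1e-9)
  means <- vapply(1:5, function(t) mean(fixed$data[t, , ]), numeric(1))
  expect_lt(sd(means) / mean(means), 1e-6)
  # no bleaching: all factors 1, output untouched
  clean <- max_project(timelapse_stack(array(0.5, c(3, 2, 8, 8)), 0.273, 60, 2))
  out <- correct_bleach(clean)
  expect_true(all(out$provenance[[2]]$factors == 1))
  expect_identical(out$data, clean$data)
  # zero-mean frame errors with the frame named
  dark <- projected_series(array(c(1, 0), c(2, 4, 4)) * 0, 0.273, 60)
  expect_error(correct_bleach(dark), "frame 1")
})

test_that("binarization separates a two-level image for any method", {
  img <- matrix(0, 32, 32); img[10:20, 10:20] <- 100
  series <- projected_series(frames_to_array(list(img, img)), 0.273, 60)
  for (b in list(binarize(series),
                 binarize(series, method = "fixed", threshold = 50))) {
    expect_true(b$binary)
    expect_equal(b$data[1, , ] > 0, img == 100)
  }
  expect_error(binarize(series, method = "fixed"), "threshold")
  dark <- projected_series(array(0, c(2, 8, 8)), 0.273, 60)
  expect_warning(binarize(dark), "all-zero")
})

test_that("binarized simulation overlaps ground-truth geometry (Jaccard >= 0.7)", {
  cfg <- test_sim_config(seed = 12L, noise_scale = 0.01)
  sim <- simulate_timelapse(cfg)
  bin <- binarize(max_project(sim$stack))
  jac <- vapply(1:10, function(t) {
    a <- bin$data[t, , ] > 0
    b <- sim$truth$geometry[t, , ]
    sum(a & b) / sum(a | b)
  }, numeric(1))
  expect_true(all(jac >= 0.7))
})

test_that("preprocessing preserves calibration metadata unchanged", {
  cfg <- test_sim_config(image_size = 128L, n_cells = 1L, n_z = 3L, seed = 3L,
                         noise_scale = 0.01, bleach_rate = 0.05,
                         drift_px_per_frame = c(1, 0))
  sim <- simulate_timelapse(cfg)
  out <- preprocess_stack(sim$stack, run_config())
  expect_equal(out$pixel_size_um, sim$stack$pixel_size_um)
  expect_equal(out$frame_interval_s, sim$stack$frame_interval_s)
  expect_true(out$binary)
  steps <- vapply(out$provenance, `[[`, "", "step")
  expect_equal(steps, c("max_project", "correct_drift", "correct_bleach",
                        "binarize"))
})

test_that("stack TIFF round-trip preserves data and calibration", {
  cfg <- test_sim_config(image_size = 64L, n_cells = 1L, n_z = 2L,
                         n_frames = 3L, seed = 5L, noise_scale = 0.01)
  sim <- simulate_timelapse(cfg)
  tmp <- file.path(tempdir(), "stack_roundtrip.tiff")
  on.exit(unlink(c(tmp, paste0(tmp, ".json"))), add = TRUE)
  write_stack(sim$stack, tmp)
  back <- read_stack(tmp)
  expect_equal(dim(back$data), dim(sim$stack$data))
  expect_equal(back$pixel_size_um, sim$stack$pixel_size_um)
  # 16-bit quantization bound
  expect_lt(max(abs(back$data - sim$stack$data)), max(sim$stack$data) / 65000)
})
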