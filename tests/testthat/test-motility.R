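test_that("persistence threshold converts seconds to frames by ceiling", {
  expect_equal(stability_threshold_frames(60), 3L)
  expect_equal(stability_threshold_frames(90), 2L)
  expect_equal(stability_threshold_frames(180), 1L)
  expect_equal(stability_threshold_frames(45, 180), 4L)
  expect_error(stability_threshold_frames(0), "frame_interval_s")
})

test_that("a static series yields zero events and an undefined index", {
  base <- matrix(FALSE, 30, 30); base[14:16, 5:25] <- TRUE
  series <- make_toy_binary_series(list(), 6, base)
  seg <- segment_cells(series, min_area_px = 20)
  ev <- detect_extensions(series, seg, min_event_px = 1L)
  expect_equal(nrow(ev$events), 0L)
  ev <- classify_stability(ev, series)
  si <- stability_index(ev, per_cell = FALSE)
  expect_true(si$undefined)
  expect_true(is.na(si$stability_index))
})

test_that("a single appearing block is one event with the right footprint", {
  base <- matrix(FALSE, 30, 30); base[14:16, 5:25] <- TRUE
  blk <- as.matrix(expand.grid(y = 11:13, x = 10:12))
  series <- make_toy_binary_series(
    list(list(onset_frame = 2, pixels = blk, lifetime_frames = 5)),
    n_frames = 10, base_mask = base)
  seg <- segment_cells(series, min_area_px = 20)
  ev <- detect_extensions(series, seg, min_event_px = 1L)
  expect_equal(nrow(ev$events), 1L)
  expect_equal(ev$events$onset_frame, 2)
  expect_equal(ev$events$n_pixels, 9)
  expect_equal(ev$events$cell_id, 1)
})

test_that("persistence is counted from onset and compared to the threshold", {
  base <- matrix(FALSE, 30, 40); base[14:16, 5:35] <- TRUE
  blk <- function(x0) as.matrix(expand.grid(y = 11:13, x = x0:(x0 + 2)))
  series <- make_toy_binary_series(list(
    list(onset_frame = 2, pixels = blk(7), lifetime_frames = 3),   # frames 2-4
    list(onset_frame = 2, pixels = blk(15), lifetime_frames = 2),  # frames 2-3
    list(onset_frame = 2, pixels = blk(23), lifetime_frames = 8)   # frames 2-9
  ), n_frames = 10, base_mask = base)
  seg <- segment_cells(series, min_area_px = 20)
  ev <- classify_stability(detect_extensions(series, seg, min_event_px = 1L),
                           series, stability_threshold_frames = 3L)
  df <- ev$events[order(ev$events$n_pixels, -ev$events$event_id), ]
  df <- ev$events
  # match events to blocks by column of footprint centroid
  cols <- vapply(ev$footprints, function(f) mean(((f - 1) %/% 30) + 1),
                 numeric(1))
  df <- df[order(cols), ]
  expect_equal(df$persistence_frames, c(3L, 2L, 8L))
  expect_equal(df$stable, c(TRUE, FALSE, TRUE))
})

test_that("stability index is stable / all, per cell and pooled", {
  base <- matrix(FALSE, 30, 40); base[14:16, 5:35] <- TRUE
  blk <- function(x0) as.matrix(expand.grid(y = 11:13, x = x0:(x0 + 2)))
  series <- make_toy_binary_series(list(
    list(onset_frame = 2, pixels = blk(7), lifetime_frames = 9),
    list(onset_frame = 3, pixels = blk(15), lifetime_frames = 1)
  ), n_frames = 10, base_mask = base)
  seg <- segment_cells(series, min_area_px = 20)
  ev <- classify_stability(detect_extensions(series, seg, min_event_px = 1L),
                           series)
  pooled <- stability_index(ev, per_cell = FALSE)
  expect_equal(pooled$stability_index, 0.5)
  per <- stability_index(ev)
  expect_equal(per$n_events, 2L)
  expect_equal(per$n_stable, 1L)
})

test_that("pipeline equals the brute-force oracle on randomized toy series", {
  set.seed(271)
  for (i in 1:30) {
    case <- random_toy_case()
    si <- pipeline_si(case$series)
    expect_equal(si$n_events, case$n_events)
    expect_equal(si$stability_index, case$oracle_si)
  }
})

test_that("threshold longer than the movie is rejected", {
  base <- matrix(FALSE, 20, 20); base[9:11, 3:17] <- TRUE
  series <- make_toy_binary_series(list(), 4, base)
  seg <- segment_cells(series, min_area_px = 20)
  ev <- detect_extensions(series, seg, min_event_px = 1L)
  expect_error(classify_stability(ev, series, stability_threshold_frames = 5L),
               "exceeds")
})

test_that("events below min_event_px or detached from cells are discarded", {
  base <- matrix(FALSE, 40, 40); base[19:21, 3:37] <- TRUE
  blk_small <- cbind(c(16, 16), c(10, 11))          # 2 px, touching base halo
  blk_far <- as.matrix(expand.grid(y = 3:5, x = 30:32))  # isolated island
  series <- make_toy_binary_series(list(
    list(onset_frame = 2, pixels = blk_small, lifetime_frames = 3),
    list(onset_frame = 2, pixels = blk_far, lifetime_frames = 3)
  ), n_frames = 6, base_mask = base)
  seg <- segment_cells(series, min_area_px = 20)
  ev <- detect_extensions(series, seg, min_event_px = 4L)
  # small block fails the size gate; far block fails prev-frame adjacency
  expect_equal(nrow(ev$events), 0L)
})

test_that("a series without registration provenance triggers a warning", {
  base <- matrix(FALSE, 30, 30); base[14:16, 5:25] <- TRUE
  data <- frames_to_array(list(base, base, base))
  series <- projected_series(data, 0.273, 60, binary = TRUE)
  seg <- segment_cells(series, min_area_px = 20)
  expect_warning(detect_extensions(series, seg), "drift")
})

test_that("stability index recovers the simulated stable fraction (clean geometry)", {
  for (sf in c(0.2, 0.8)) {
    sim <- simulate_timelapse(test_sim_config(stable_fraction = sf,
                                              seed = 50L + round(10 * sf)))
    series <- truth_geometry_series(sim$truth)
    seg <- segment_cells(series)
    ev <- classify_stability(detect_extensions(series, seg, min_event_px = 1L),
                             series)
    si <- stability_index(ev, per_cell = FALSE)
    expect_gte(si$n_events, 50)
    expect_lt(abs(si$stability_index - sim$truth$stability_index$value), 0.10)
  }
})

test_that("stability index is monotone in the simulated stable fraction", {
  vals <- vapply(c(0.2, 0.5, 0.8), function(sf) {
    sim <- simulate_timelapse(test_sim_config(stable_fraction = sf, seed = 77L))
    series <- truth_geometry_series(sim$truth)
    seg <- segment_cells(series)
    ev <- classify_stability(detect_extensions(series, seg, min_event_px = 1L),
                             series)
    stability_index(ev, per_cell = FALSE)$stability_index
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("stability index is invariant under global intensity rescaling", {
  cfg <- test_sim_config(image_size = 256L, n_cells = 2L, seed = 13L,
                         noise_scale = 0.01)
  sim <- simulate_timelapse(cfg)
  run <- function(stack) {
    series <- binarize(max_project(stack))
    series$provenance <- c(series$provenance,
                           list(list(step = "correct_drift",
                                     shifts = matrix(0, 10, 2))))
    seg <- segment_cells(series)
    ev <- classify_stability(detect_extensions(series, seg), series)
    stability_index(ev, per_cell = FALSE)$stability_index
  }
  scaled <- sim$stack
  scaled$data <- scaled$data * 2.7
  expect_equal(run(sim$stack), run(scaled))
})
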