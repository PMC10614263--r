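# Rasterization primitives ---------------------------------------------------

# linear indices of a filled disk, clipped to the image
raster_disk_idx <- function(ny, nx, cy, cx, r) {
  y0 <- max(1L, floor(cy - r)); y1 <- min(ny, ceiling(cy + r))
  x0 <- max(1L, floor(cx - r)); x1 <- min(nx, ceiling(cx + r))
  if (y0 > y1 || x0 > x1) return(integer(0))
  ys <- y0:y1; xs <- x0:x1
  yy <- matrix(ys, length(ys), length(xs))
  xx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  sel <- (yy - cy)^2 + (xx - cx)^2 <= r^2
  (xx[sel] - 1L) * ny + yy[sel]
}

# linear indices of pixels within half_width of the segment p0 -> p1
raster_segment_idx <- function(ny, nx, p0, p1, half_width) {
  pad <- ceiling(half_width) + 1
  y0 <- max(1L, floor(min(p0[1], p1[1]) - pad))
  y1 <- min(ny, ceiling(max(p0[1], p1[1]) + pad))
  x0 <- max(1L, floor(min(p0[2], p1[2]) - pad))
  x1 <- min(nx, ceiling(max(p0[2], p1[2]) + pad))
  if (y0 > y1 || x0 > x1) return(integer(0))
  ys <- y0:y1; xs <- x0:x1
  yy <- matrix(ys, length(ys), length(xs))
  xx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  v <- p1 - p0
  len2 <- sum(v^2)
  if (len2 < 1e-12) {
    d2 <- (yy - p0[1])^2 + (xx - p0[2])^2
  } else {
    tt <- ((yy - p0[1]) * v[1] + (xx - p0[2]) * v[2]) / len2
    tt <- pmin(1, pmax(0, tt))
    d2 <- (yy - (p0[1] + tt * v[1]))^2 + (xx - (p0[2] + tt * v[2]))^2
  }
  sel <- d2 <= half_width^2
  (xx[sel] - 1L) * ny + yy[sel]
}

# open annulus (phagocytic cup): ring with an angular gap facing `gap_dir`
raster_cup_idx <- function(ny, nx, cy, cx, r_outer, r_inner, gap_dir,
                           gap_half_angle = pi / 5) {
  y0 <- max(1L, floor(cy - r_outer)); y1 <- min(ny, ceiling(cy + r_outer))
  x0 <- max(1L, floor(cx - r_outer)); x1 <- min(nx, ceiling(cx + r_outer))
  if (y0 > y1 || x0 > x1) return(list(wall = integer(0), cavity = integer(0)))
  ys <- y0:y1; xs <- x0:x1
  yy <- matrix(ys, length(ys), length(xs))
  xx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  d2 <- (yy - cy)^2 + (xx - cx)^2
  ang <- atan2(yy - cy, xx - cx)
  dang <- abs(atan2(sin(ang - gap_dir), cos(ang - gap_dir)))
  wall <- d2 <= r_outer^2 & d2 >= r_inner^2 & dang > gap_half_angle
  cavity <- d2 < r_inner^2
  list(wall = (xx[wall] - 1L) * ny + yy[wall],
       cavity = (xx[cavity] - 1L) * ny + yy[cavity])
}

# Cell geometry ---------------------------------------------------------------

# grow one cell: disk soma plus piecewise-linear (optionally branched)
# processes; returns base pixel indices, polyline length (um) and tip list
grow_cell <- function(cell_id, cy, cx, cfg, ny, nx) {
  ps <- cfg$pixel_size_um
  soma_r <- cfg$soma_radius_um / ps
  half_w <- cfg$process_width_um / ps / 2
  base_idx <- raster_disk_idx(ny, nx, cy, cx, soma_r)
  tips <- list()
  base_len_um <- 0
  dirs <- seq(0, 2 * pi, length.out = cfg$n_primary_processes + 1L)[-1L] +
    runif(1, 0, 2 * pi / cfg$n_primary_processes)
  n_seg <- 3L
  seg_len <- cfg$process_length_um / ps / n_seg
  for (d in dirs) {
    pos <- c(cy + soma_r * sin(d), cx + soma_r * cos(d))
    ang <- d
    joint <- NULL; joint_ang <- NA
    for (s in seq_len(n_seg)) {
      ang <- ang + runif(1, -0.3, 0.3)
      nxt <- pos + seg_len * c(sin(ang), cos(ang))
      base_idx <- c(base_idx, raster_segment_idx(ny, nx, pos, nxt, half_w))
      base_len_um <- base_len_um + seg_len * ps
      pos <- nxt
      if (s == 1L) { joint <- pos; joint_ang <- ang }
    }
    tips[[length(tips) + 1L]] <- list(pos = pos, dir = ang, active = TRUE,
                                      n_grown = 0L)
    if (runif(1) < cfg$branch_prob) {
      bang <- joint_ang + sample(c(-1, 1), 1L) * runif(1, 0.6, 1.0)
      bpos <- joint
      for (s in 1:2) {
        bang <- bang + runif(1, -0.3, 0.3)
        nxt <- bpos + seg_len * c(sin(bang), cos(bang))
        base_idx <- c(base_idx, raster_segment_idx(ny, nx, bpos, nxt, half_w))
        base_len_um <- base_len_um + seg_len * ps
        bpos <- nxt
      }
      tips[[length(tips) + 1L]] <- list(pos = bpos, dir = bang, active = TRUE,
                                        n_grown = 0L)
    }
  }
  list(cell_id = cell_id, cy = cy, cx = cx,
       base_idx = unique(base_idx), base_len_um = base_len_um, tips = tips)
}

# Simulator -------------------------------------------------------------------

#' Simulate a ground-truthed microglial time-lapse stack
#'
#' Renders disk-soma cells with branched processes, spawns extension events at
#' process tips with known stability labels, and produces both the noisy 4D
#' stack (geometry -> PSF blur -> drift -> bleach -> shot noise, in that
#' order) and a complete ground-truth record: every event with its onset,
#' footprint, lifetime and label; per-frame true process length; the true
#' per-cell and pooled stability index; the applied drift vectors and bleach
#' factors; and the clean projected binary geometry.
#'
#' Event onsets are confined to frames `2 .. n_frames - 2` so that every
#' event labeled stable is observable for at least three frames; stable
#' extensions persist (and advance the tip) through the final frame, unstable
#' ones retract after `unstable_lifetime_frames`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `stack` (a [timelapse_stack()]) and `truth`
#'   (class `ground_truth`): see Details.
#' @export
simulate_timelapse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_timelapse_impl(config))
}

simulate_timelapse_impl <- function(cfg) {
  n <- cfg$image_size; ny <- n; nx <- n
  Tn <- cfg$n_frames
  ps <- cfg$pixel_size_um

  # --- place cells on a jittered grid ---
  cells <- list()
  if (cfg$n_cells > 0L) {
    g <- ceiling(sqrt(cfg$n_cells))
    spacing <- n / g
    k <- 0L
    for (i in seq_len(g)) for (j in seq_len(g)) {
      if (k >= cfg$n_cells) next
      k <- k + 1L
      cy <- (i - 0.5) * spacing + runif(1, -0.06, 0.06) * spacing
      cx <- (j - 0.5) * spacing + runif(1, -0.06, 0.06) * spacing
      cells[[k]] <- grow_cell(k, cy, cx, cfg, ny, nx)
    }
  }

  # --- optional phagocytic cup at one tip per selected cell ---
  cup_area_um2 <- rep(NA_real_, length(cells))
  for (k in seq_along(cells)) {
    if (runif(1) >= cfg$cup_fraction) next
    tips <- cells[[k]]$tips
    ti <- sample.int(length(tips), 1L)
    tip <- tips[[ti]]
    r_out <- cfg$cup_radius_um / ps
    r_in <- max(1.5, r_out - cfg$process_width_um / ps * 1.5)
    ctr <- tip$pos + (r_out + 1) * c(sin(tip$dir), cos(tip$dir))
    cup <- raster_cup_idx(ny, nx, ctr[1], ctr[2], r_out, r_in,
                          gap_dir = tip$dir + pi)
    if (length(cup$wall) == 0L) next
    cells[[k]]$base_idx <- unique(c(cells[[k]]$base_idx, cup$wall))
    cells[[k]]$tips[[ti]]$active <- FALSE
    cup_area_um2[k] <- length(cup$cavity) * ps^2
  }

  base_mask <- matrix(FALSE, ny, nx)
  for (cl in cells) base_mask[cl$base_idx] <- TRUE

  # --- spawn extension events chronologically ---
  half_w <- cfg$process_width_um / ps / 2
  ext_len_px <- cfg$extension_length_um / ps
  events <- list()
  spawn_last <- Tn - 2L                    # stable labels need >= 3 frames
  occupied <- base_mask                    # evolves within the spawn loop
  active_transients <- list()              # idx + end frame
  nbr_off8 <- function(ny) c(-1L, 1L, -ny, ny, -ny - 1L, -ny + 1L,
                             ny - 1L, ny + 1L)
  prev_mask <- base_mask                   # full mask of frame t-1
  for (t in 2:spawn_last) {
    # occupancy at frame t: base + stable-so-far + transients alive at t
    alive <- vapply(active_transients, function(a) a$end >= t, logical(1))
    active_transients <- active_transients[alive]
    occ <- occupied
    for (a in active_transients) occ[a$idx] <- TRUE
    new_this_frame <- matrix(FALSE, ny, nx)
    for (k in seq_along(cells)) {
      for (ti in seq_along(cells[[k]]$tips)) {
        tip <- cells[[k]]$tips[[ti]]
        if (!tip$active) next
        if (runif(1) >= cfg$extension_prob) next
        ang <- tip$dir + runif(1, -0.6, 0.6)
        p1 <- tip$pos + ext_len_px * c(sin(ang), cos(ang))
        if (p1[1] < 6 || p1[1] > ny - 5 || p1[2] < 6 || p1[2] > nx - 5) {
          cells[[k]]$tips[[ti]]$active <- FALSE
          next
        }
        seg_idx <- raster_segment_idx(ny, nx, tip$pos, p1, half_w)
        # a footprint pixel must be new relative to both the current
        # occupancy and the previous frame (a pixel vacated by a transient
        # only this frame is not "new" to a frame-difference detector)
        foot <- seg_idx[!occ[seg_idx] & !prev_mask[seg_idx]]
        if (length(foot) < 6L) next
        # keep ground truth 1:1 with detectable events: the footprint must
        # be one 8-connected blob, not abutting another footprint born this
        # frame (which would merge on detection)
        if (!is_connected8(foot, ny, nx)) next
        halo <- unique(as.vector(outer(foot, c(0L, nbr_off8(ny)), `+`)))
        halo <- halo[halo >= 1L & halo <= ny * nx]
        if (any(new_this_frame[halo])) next
        stable <- runif(1) < cfg$stable_fraction
        lifetime <- if (stable) Tn - t + 1L else
          min(cfg$unstable_lifetime_frames, Tn - t + 1L)
        events[[length(events) + 1L]] <- list(
          cell_id = k, onset_frame = t, seg_idx = seg_idx, foot_idx = foot,
          lifetime = lifetime, stable = stable,
          length_um = cfg$extension_length_um)
        new_this_frame[foot] <- TRUE
        occ[seg_idx] <- TRUE
        if (stable) {
          occupied[seg_idx] <- TRUE
          cells[[k]]$tips[[ti]]$pos <- p1
          cells[[k]]$tips[[ti]]$dir <- ang
          ng <- cells[[k]]$tips[[ti]]$n_grown + 1L
          cells[[k]]$tips[[ti]]$n_grown <- ng
          if (ng >= 3L) cells[[k]]$tips[[ti]]$active <- FALSE
        } else {
          active_transients[[length(active_transients) + 1L]] <-
            list(idx = seg_idx, end = t + lifetime - 1L)
        }
      }
    }
    prev_mask <- occ                       # occ now includes frame-t spawns
  }

  # --- per-frame clean projected geometry and true process length ---
  geometry <- array(FALSE, dim = c(Tn, ny, nx))
  proc_len <- matrix(0, nrow = max(1L, length(cells)), ncol = Tn)
  base_len <- vapply(cells, `[[`, numeric(1), "base_len_um")
  for (t in seq_len(Tn)) {
    m <- base_mask
    for (ev in events) {
      ev_end <- if (ev$stable) Tn else ev$onset_frame + ev$lifetime - 1L
      if (t >= ev$onset_frame && t <= ev_end) {
        m[ev$seg_idx] <- TRUE
        proc_len[ev$cell_id, t] <- proc_len[ev$cell_id, t] + ev$length_um
      }
    }
    if (length(cells)) proc_len[, t] <- proc_len[, t] + base_len
    geometry[t, , ] <- m
  }
  if (!length(cells)) proc_len <- matrix(numeric(0), 0, Tn)

  # --- render: geometry -> PSF -> z-profile -> artifacts ---
  sigma_px <- cfg$psf_sigma_um / ps
  zc <- (cfg$n_z + 1) / 2
  zsig <- max(1, cfg$n_z / 5)
  zw <- exp(-0.5 * ((seq_len(cfg$n_z) - zc) / zsig)^2)
  data <- array(0, dim = c(Tn, cfg$n_z, ny, nx))
  for (t in seq_len(Tn)) {
    img <- geometry[t, , ] * 1.0
    if (sigma_px > 0.05) img <- EBImage::gblur(img, sigma = sigma_px)
    for (z in seq_len(cfg$n_z))
      data[t, z, , ] <- img * zw[z] + cfg$background
  }
  stack <- timelapse_stack(data, cfg$pixel_size_um, cfg$frame_interval_s,
                           cfg$z_step_um)
  stack <- apply_artifacts(stack, drift = cfg$drift_px_per_frame,
                           bleach_rate = cfg$bleach_rate,
                           noise_scale = cfg$noise_scale,
                           fill = cfg$background)

  # --- ground-truth record ---
  ev_df <- if (length(events)) data.frame(
    cell_id = vapply(events, `[[`, numeric(1), "cell_id"),
    onset_frame = vapply(events, `[[`, numeric(1), "onset_frame"),
    n_pixels = vapply(events, function(e) length(e$foot_idx), numeric(1)),
    lifetime_frames = vapply(events, `[[`, numeric(1), "lifetime"),
    stable = vapply(events, `[[`, logical(1), "stable")
  ) else data.frame(cell_id = numeric(0), onset_frame = numeric(0),
                    n_pixels = numeric(0), lifetime_frames = numeric(0),
                    stable = logical(0))
  cells_df <- if (length(cells)) data.frame(
    cell_id = vapply(cells, `[[`, numeric(1), "cell_id"),
    center_y = vapply(cells, `[[`, numeric(1), "cy"),
    center_x = vapply(cells, `[[`, numeric(1), "cx"),
    soma_radius_um = cfg$soma_radius_um,
    soma_perimeter_um = 2 * pi * cfg$soma_radius_um,
    cup_area_um2 = cup_area_um2,
    base_process_length_um = base_len
  ) else data.frame(cell_id = numeric(0), center_y = numeric(0),
                    center_x = numeric(0), soma_radius_um = numeric(0),
                    soma_perimeter_um = numeric(0), cup_area_um2 = numeric(0),
                    base_process_length_um = numeric(0))
  si <- list(value = if (nrow(ev_df)) mean(ev_df$stable) else NA_real_,
             undefined = nrow(ev_df) == 0L)
  truth <- structure(list(
    cells = cells_df,
    events = ev_df,
    event_footprints = lapply(events, `[[`, "foot_idx"),
    process_length_um = proc_len,
    stability_index = si,
    drift = outer(0:(Tn - 1L), cfg$drift_px_per_frame),
    bleach = exp(-cfg$bleach_rate * (0:(Tn - 1L))),
    geometry = geometry,
    config = cfg), class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d cells, %d events (%d stable), true SI = %s\n",
              nrow(x$cells), nrow(x$events), sum(x$events$stable),
              if (x$stability_index$undefined) "undefined"
              else sprintf("%.3f", x$stability_index$value)))
  invisible(x)
}

#' Clean projected geometry of a simulation as a binary series
#'
#' Convenience accessor: wraps the ground-truth per-frame binary geometry in a
#' [projected_series()] (marked registered, since the clean geometry carries
#' no drift), ready for the motility stage. Useful for validating detection
#' against truth without rendering noise.
#'
#' @param truth A `ground_truth` object from [simulate_timelapse()].
#' @return A binary [projected_series()].
#' @export
truth_geometry_series <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  cfg <- truth$config
  Tn <- cfg$n_frames
  projected_series(truth$geometry * 1.0, cfg$pixel_size_um,
                   cfg$frame_interval_s,
                   provenance = list(list(step = "correct_drift",
                                          shifts = matrix(0, Tn, 2),
                                          synthetic = TRUE)),
                   binary = TRUE)
}
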