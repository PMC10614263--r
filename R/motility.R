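#' Persistence threshold in frames
#'
#' Converts the physical persistence criterion (an extension must hold its
#' position for at least `min_persistence_s` seconds -- 3 minutes by
#' convention) into a frame count for a given acquisition interval:
#' `ceiling(min_persistence_s / frame_interval_s)`. At the canonical 60 s
#' interval this is 3 frames.
#'
#' @param frame_interval_s Seconds between frames (> 0).
#' @param min_persistence_s Minimum persistence in seconds (default 180).
#' @return Integer number of frames.
#' @export
stability_threshold_frames <- function(frame_interval_s,
                                       min_persistence_s = 180) {
  check_positive_scalar(frame_interval_s, "frame_interval_s")
  check_positive_scalar(min_persistence_s, "min_persistence_s")
  as.integer(ceiling(min_persistence_s / frame_interval_s))
}

#' Detect new process-extension events
#'
#' For every frame `t >= 2`, pixels present at `t` but absent at `t - 1` are
#' grouped into connected components. Components of at least `min_event_px`
#' pixels that touch the previous frame's foreground (a true extension grows
#' out of existing structure; isolated appearances are noise) become
#' extension events, assigned to the nearest segmented cell.
#'
#' @param series A registered, binarized [projected_series()]. A series
#'   without drift-correction provenance triggers a warning, not an error.
#' @param seg A [segment_cells()] result for the same field.
#' @param min_event_px Minimum event footprint, pixels (default 4: a
#'   single-pixel shot-noise flicker must not count as an extension).
#' @return An object of class `extension_events`: a data frame of events
#'   (`event_id`, `cell_id`, `onset_frame`, `n_pixels`) plus the pixel
#'   footprint of each event. Persistence is filled in by
#'   [classify_stability()].
#' @export
detect_extensions <- function(series, seg, min_event_px = 4L) {
  stopifnot(inherits(series, "projected_series"),
            inherits(seg, "cell_segmentation"))
  if (!series$binary)
    stop("`series` must be binary (see binarize())", call. = FALSE)
  Tn <- n_frames(series)
  if (Tn < 2L) stop("need at least 2 frames to detect extensions",
                    call. = FALSE)
  if (!has_provenance_step(series, "correct_drift"))
    warning("series has no drift-correction provenance; ",
            "uncorrected drift will inflate event counts")
  ny <- dim(series$data)[2]; nx <- dim(series$data)[3]

  # nearest-cell map: argmin over per-cell distance transforms
  n_cells <- length(seg$cells)
  nearest <- matrix(0L, ny, nx)
  if (n_cells > 0L) {
    best_d <- matrix(Inf, ny, nx)
    for (cl in seg$cells) {
      m <- mask_from_idx(cl$full_idx, ny, nx)
      dmap <- EBImage::distmap(1 - m)
      upd <- dmap < best_d
      nearest[upd] <- cl$cell_id
      best_d[upd] <- dmap[upd]
    }
  }

  events <- list()
  footprints <- list()
  prev <- get_frame(series, 1L) > 0
  for (t in 2:Tn) {
    cur <- get_frame(series, t) > 0
    new_px <- cur & !prev
    if (any(new_px)) {
      prev_dil <- EBImage::dilate(prev * 1.0, box3()) > 0.5
      lab <- label8(new_px)
      for (k in seq_len(max(lab))) {
        idx <- which(lab == k)
        if (length(idx) < min_event_px) next
        if (!any(prev_dil[idx])) next        # must grow out of structure
        cid <- 0L
        if (n_cells > 0L) {
          cand <- nearest[idx]
          cand <- cand[cand > 0L]
          if (length(cand)) cid <- as.integer(names(which.max(table(cand))))
        }
        if (cid == 0L) next                  # touches no cell: discard
        events[[length(events) + 1L]] <- data.frame(
          cell_id = cid, onset_frame = t, n_pixels = length(idx))
        footprints[[length(footprints) + 1L]] <- idx
      }
    }
    prev <- cur
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(cell_id = integer(0), onset_frame = integer(0),
               n_pixels = integer(0))
  if (nrow(ev)) ev <- cbind(event_id = seq_len(nrow(ev)), ev) else
    ev <- cbind(data.frame(event_id = integer(0)), ev)
  structure(list(events = ev, footprints = footprints,
                 dim = c(ny, nx), n_frames = Tn),
            class = "extension_events")
}

#' @export
print.extension_events <- function(x, ...) {
  cat(sprintf("<extension_events> %d events over %d frames", nrow(x$events),
              x$n_frames))
  if ("stable" %in% names(x$events))
    cat(sprintf(" (%d stable)", sum(x$events$stable)))
  cat("\n")
  invisible(x)
}

#' Classify extension persistence and stability
#'
#' For each detected event, persistence is the largest `k` such that in every
#' frame `onset .. onset + k - 1` at least `overlap_fraction` of the onset
#' footprint is still occupied (after dilating the frame mask by 1 px, a
#' jitter tolerance: exact pixel matching would misclassify under 1-px
#' breathing of the mask). Persistence is counted from the onset frame
#' inclusively, so an extension seen in three consecutive frames at a 60-s
#' interval has held its position for 3 minutes. Events with persistence at
#' or above `stability_threshold_frames` are stable.
#'
#' @param ev An [detect_extensions()] result.
#' @param series The same binary series events were detected on.
#' @param stability_threshold_frames Frames required for stability (default
#'   3; see [stability_threshold_frames()]).
#' @param overlap_fraction Fraction of the onset footprint that must remain
#'   occupied (default 0.5).
#' @param dilate_px Mask dilation tolerance in pixels (default 1; 0 disables).
#' @return `ev` with `persistence_frames` and `stable` columns filled in.
#' @export
classify_stability <- function(ev, series, stability_threshold_frames = 3L,
                               overlap_fraction = 0.5, dilate_px = 1L) {
  stopifnot(inherits(ev, "extension_events"),
            inherits(series, "projected_series"))
  Tn <- n_frames(series)
  check_count(stability_threshold_frames, "stability_threshold_frames",
              min = 1L)
  if (stability_threshold_frames > Tn)
    stop("`stability_threshold_frames` exceeds the number of frames",
         call. = FALSE)
  check_probability(overlap_fraction, "overlap_fraction")
  # precompute (dilated) frame masks once
  masks <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    m <- get_frame(series, t) > 0
    if (dilate_px >= 1L)
      m <- EBImage::dilate(m * 1.0,
                           EBImage::makeBrush(2L * as.integer(dilate_px) + 1L,
                                              "box")) > 0.5
    masks[[t]] <- m
  }
  n_ev <- nrow(ev$events)
  persistence <- integer(n_ev)
  for (i in seq_len(n_ev)) {
    onset <- ev$events$onset_frame[i]
    foot <- ev$footprints[[i]]
    k <- 0L
    for (t in onset:Tn) {
      if (mean(masks[[t]][foot]) >= overlap_fraction) k <- k + 1L else break
    }
    persistence[i] <- max(k, 1L)   # present at onset by construction
  }
  ev$events$persistence_frames <- persistence
  ev$events$stable <- persistence >= stability_threshold_frames
  ev$stability_threshold_frames <- as.integer(stability_threshold_frames)
  ev
}

#' Stability index: stable extensions over all extensions
#'
#' The motility endpoint: the number of stable extension events divided by
#' the number of all extension events, per cell or pooled over the field.
#' Lower values indicate more restless, less stable processes. Cells (or a
#' field) with zero events get an undefined index (`NA` with the `undefined`
#' flag set) rather than a number.
#'
#' @param ev A completed [classify_stability()] result.
#' @param per_cell `TRUE` for one row per cell, `FALSE` for a single pooled
#'   row (`cell_id = NA`).
#' @param cell_ids Optional cell ids to report (default: every cell with at
#'   least one event).
#' @return A data frame with columns `cell_id`, `n_events`, `n_stable`,
#'   `stability_index`, `undefined`.
#' @export
stability_index <- function(ev, per_cell = TRUE, cell_ids = NULL) {
  stopifnot(inherits(ev, "extension_events"))
  if (!"stable" %in% names(ev$events))
    stop("events are not classified; run classify_stability() first",
         call. = FALSE)
  df <- ev$events
  if (!per_cell) {
    n <- nrow(df); ns <- sum(df$stable)
    return(data.frame(cell_id = NA_integer_, n_events = n, n_stable = ns,
                      stability_index = if (n > 0) ns / n else NA_real_,
                      undefined = n == 0L))
  }
  ids <- if (is.null(cell_ids)) sort(unique(df$cell_id)) else cell_ids
  out <- lapply(ids, function(cid) {
    sub <- df[df$cell_id == cid, , drop = FALSE]
    n <- nrow(sub); ns <- sum(sub$stable)
    data.frame(cell_id = cid, n_events = n, n_stable = ns,
               stability_index = if (n > 0) ns / n else NA_real_,
               undefined = n == 0L)
  })
  if (length(out)) do.call(rbind, out) else
    data.frame(cell_id = integer(0), n_events = integer(0),
               n_stable = integer(0), stability_index = numeric(0),
               undefined = logical(0))
}
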