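# Topology-preserving 2D thinning (Zhang-Suen), vectorized over the image.
# No installed package provides binary skeletonization, so it lives here.
thin_mask <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  pad <- matrix(FALSE, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- mask
  core <- function(p, dy, dx) p[(2L + dy):(ny + 1L + dy),
                                (2L + dx):(nx + 1L + dx)]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad
      P2 <- core(p, -1L, 0L); P3 <- core(p, -1L, 1L); P4 <- core(p, 0L, 1L)
      P5 <- core(p, 1L, 1L);  P6 <- core(p, 1L, 0L);  P7 <- core(p, 1L, -1L)
      P8 <- core(p, 0L, -1L); P9 <- core(p, -1L, -1L)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
           (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      cur <- core(p, 0L, 0L)
      if (step == 1L) {
        del <- cur & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        del <- cur & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(del)) {
        changed <- TRUE
        inner <- pad[2:(ny + 1L), 2:(nx + 1L)]
        inner[del] <- FALSE
        pad[2:(ny + 1L), 2:(nx + 1L)] <- inner
      }
    }
    if (!changed) break
  }
  pad[2:(ny + 1L), 2:(nx + 1L)]
}

# 8-neighbor count for every skeleton pixel
neighbor_count <- function(skel) {
  ny <- nrow(skel); nx <- ncol(skel)
  pad <- matrix(0L, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- skel
  acc <- matrix(0L, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    acc <- acc + pad[(2L + dy):(ny + 1L + dy), (2L + dx):(nx + 1L + dx)]
  }
  acc
}

# skeleton graph degree with redundant diagonals removed: a diagonal edge is
# dropped when either of its corner axial pixels is itself in the skeleton
# (connectivity already runs through it). Thinning leaves staircase
# triangles; without this rule every triangle is walked as three segments
# and length is badly overcounted.
graph_degree <- function(skel) {
  ny <- nrow(skel); nx <- ncol(skel)
  pad <- matrix(FALSE, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- skel
  sh <- function(dy, dx) pad[(2L + dy):(ny + 1L + dy),
                             (2L + dx):(nx + 1L + dx)]
  acc <- sh(-1L, 0L) + sh(1L, 0L) + sh(0L, -1L) + sh(0L, 1L)
  for (dy in c(-1L, 1L)) for (dx in c(-1L, 1L)) {
    acc <- acc + (sh(dy, dx) & !sh(dy, 0L) & !sh(0L, dx))
  }
  acc
}

# remove terminal chains with fewer than `min_px` pixels before a junction
# (thinning artifacts inflate endpoint counts)
prune_spurs <- function(skel, min_px = 2L) {
  repeat {
    deg <- graph_degree(skel)
    ends <- which(skel & deg == 1L)
    removed <- FALSE
    ny <- nrow(skel)
    for (e in ends) {
      if (!skel[e]) next
      ey <- ((e - 1L) %% ny) + 1L; ex <- ((e - 1L) %/% ny) + 1L
      chain <- e
      cy <- ey; cx <- ex; py <- NA; px_ <- NA
      hit_junction <- FALSE
      while (length(chain) < min_px) {
        nb <- neighbors_of(skel, cy, cx, exclude = c(py, px_))
        if (nrow(nb) == 0L) break
        if (nrow(nb) > 1L) { hit_junction <- TRUE; break }
        d <- deg[nb[1, 1], nb[1, 2]]
        if (d >= 3L) { hit_junction <- TRUE; break }
        py <- cy; px_ <- cx
        cy <- nb[1, 1]; cx <- nb[1, 2]
        chain <- c(chain, (cx - 1L) * ny + cy)
      }
      if (hit_junction && length(chain) < min_px) {
        skel[chain] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  skel
}

# coordinates of graph neighbors of (y, x) under the reduced adjacency of
# graph_degree(), optionally excluding one pixel
neighbors_of <- function(skel, y, x, exclude = c(NA, NA)) {
  ny <- nrow(skel); nx <- ncol(skel)
  out <- matrix(integer(0), 0, 2)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    yy <- y + dy; xx <- x + dx
    if (yy < 1L || yy > ny || xx < 1L || xx > nx) next
    if (!skel[yy, xx]) next
    if (dy != 0L && dx != 0L) {            # redundant diagonal?
      ay <- skel[yy, x]; ax <- skel[y, xx]
      if (isTRUE(ay) || isTRUE(ax)) next
    }
    if (!is.na(exclude[1]) && yy == exclude[1] && xx == exclude[2]) next
    out <- rbind(out, c(yy, xx))
  }
  out
}

# trace the skeleton into polyline segments between nodes (endpoints and
# branch points); each 8-adjacency edge is walked exactly once.
# step length: 1 px axial, sqrt(2) px diagonal. Thinning erodes free line
# ends by roughly the stroke half-width, so each endpoint gets a cap from
# `end_caps` (the local mask radius there, from a distance transform).
trace_segments <- function(skel, end_caps = NULL) {
  ny <- nrow(skel)
  deg <- graph_degree(skel)
  is_node <- skel & (deg == 1L | deg >= 3L)
  visited <- new.env(hash = TRUE)
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  segs <- list()
  # polyline length with interior vertices smoothed (3-point running mean):
  # removes the staircase bias of digital paths; straight paths unaffected
  path_length <- function(path) {
    yy <- ((path - 1L) %% ny) + 1L
    xx <- ((path - 1L) %/% ny) + 1L
    n <- length(path)
    if (n < 2L) return(0)
    if (n >= 3L) {
      ys <- yy; xs <- xx
      mid <- 2:(n - 1L)
      ys[mid] <- (yy[mid - 1L] + yy[mid] + yy[mid + 1L]) / 3
      xs[mid] <- (xx[mid - 1L] + xx[mid] + xx[mid + 1L]) / 3
      yy <- ys; xx <- xs
    }
    sum(sqrt(diff(yy)^2 + diff(xx)^2))
  }
  walk <- function(start_idx, next_y, next_x) {
    sy <- ((start_idx - 1L) %% ny) + 1L
    sx <- ((start_idx - 1L) %/% ny) + 1L
    path <- c(start_idx)
    cy <- sy; cx <- sx
    ty <- next_y; tx <- next_x
    repeat {
      tidx <- (tx - 1L) * ny + ty
      k <- ekey(path[length(path)], tidx)
      if (!is.null(visited[[k]])) return(NULL)
      visited[[k]] <- TRUE
      path <- c(path, tidx)
      if (is_node[ty, tx]) break
      nb <- neighbors_of(skel, ty, tx, exclude = c(cy, cx))
      if (nrow(nb) == 0L) break
      # prefer an unvisited edge (relevant only in rare dense configurations)
      pick <- 1L
      for (r in seq_len(nrow(nb))) {
        cand <- (nb[r, 2] - 1L) * ny + nb[r, 1]
        if (is.null(visited[[ekey(tidx, cand)]])) { pick <- r; break }
      }
      cy <- ty; cx <- tx
      ty <- nb[pick, 1]; tx <- nb[pick, 2]
    }
    list(pixels = path, length_px = path_length(path))
  }
  node_idx <- which(is_node)
  for (nidx in node_idx) {
    yy <- ((nidx - 1L) %% ny) + 1L; xx <- ((nidx - 1L) %/% ny) + 1L
    nb <- neighbors_of(skel, yy, xx)
    for (r in seq_len(nrow(nb))) {
      sg <- walk(nidx, nb[r, 1], nb[r, 2])
      if (!is.null(sg)) segs[[length(segs) + 1L]] <- sg
    }
  }
  # pure cycles (no node anywhere on them), e.g. cup rings
  remaining <- which(skel & deg == 2L)
  for (ridx in remaining) {
    yy <- ((ridx - 1L) %% ny) + 1L; xx <- ((ridx - 1L) %/% ny) + 1L
    nb <- neighbors_of(skel, yy, xx)
    for (r in seq_len(nrow(nb))) {
      cand <- (nb[r, 2] - 1L) * ny + nb[r, 1]
      if (is.null(visited[[ekey(ridx, cand)]])) {
        sg <- walk(ridx, nb[r, 1], nb[r, 2])
        if (!is.null(sg)) segs[[length(segs) + 1L]] <- sg
      }
    }
  }
  # endpoint caps at each degree-1 terminus
  if (length(segs)) {
    for (i in seq_along(segs)) {
      p <- segs[[i]]$pixels
      caps <- 0
      for (idx in c(p[1], p[length(p)])) {
        yy <- ((idx - 1L) %% ny) + 1L; xx <- ((idx - 1L) %/% ny) + 1L
        if (deg[yy, xx] == 1L)
          caps <- caps + if (is.null(end_caps)) 0.5 else end_caps[yy, xx]
      }
      segs[[i]]$length_px <- segs[[i]]$length_px + caps
    }
  }
  segs
}

#' Skeletonize a segmented cell and measure its processes
#'
#' A tracing proxy for manual neurite reconstruction: the cell mask minus the
#' soma core is thinned to a 1-px skeleton (Zhang-Suen), short spurs are
#' pruned, and the skeleton is decomposed into polyline segments between
#' branch points (>= 3 skeleton neighbors) and endpoints (exactly 1).
#' Segment lengths accumulate 1 pixel per axial step and sqrt(2) per diagonal
#' step, plus a half-pixel cap at each endpoint.
#'
#' @param seg A [segment_cells()] result.
#' @param cell_id Cell label (must not touch the image border).
#' @param pixel_size_um Micrometres per pixel (default: from `seg`).
#' @param prune_spur_px Spurs shorter than this many pixels are removed
#'   before counting (default 2).
#' @return An object of class `cell_skeleton`: skeleton pixel set, segments,
#'   `total_length_um`, `n_branch_points`, `n_endpoints`. A soma-only cell
#'   yields an empty skeleton with zero length (valid).
#' @export
skeletonize_cell <- function(seg, cell_id, pixel_size_um = seg$pixel_size_um,
                             prune_spur_px = 2L) {
  stopifnot(inherits(seg, "cell_segmentation"))
  cl <- get_cell(seg, cell_id)
  if (cl$touches_border)
    stop(sprintf("cell %d touches the image border; not skeletonized",
                 cell_id), call. = FALSE)
  ny <- nrow(seg$label_image); nx <- ncol(seg$label_image)
  proc <- mask_from_idx(setdiff(cl$full_idx, cl$soma_idx), ny, nx)
  empty <- structure(list(cell_id = cell_id, skeleton_idx = integer(0),
                          segments = list(), total_length_um = 0,
                          n_branch_points = 0L, n_endpoints = 0L,
                          dim = c(ny, nx)), class = "cell_skeleton")
  if (!any(proc)) return(empty)
  skel <- thin_mask(proc)
  skel <- prune_spurs(skel, min_px = prune_spur_px)
  if (!any(skel)) return(empty)
  deg <- graph_degree(skel)
  # endpoint cap: local stroke radius (skeleton stops ~radius short of the
  # mask boundary at free ends); floor of half a pixel
  dt <- EBImage::distmap(proc * 1.0)
  caps <- matrix(pmax(0.5, as.numeric(dt) - 0.5), ny, nx)
  segs <- trace_segments(skel, end_caps = caps)
  total_px <- sum(vapply(segs, `[[`, numeric(1), "length_px"))
  # a thick crossing thins to a small cluster of high-degree pixels: count
  # branch points as 8-connected clusters, not raw pixels
  branch_mask <- skel & deg >= 3L
  n_branch <- if (any(branch_mask)) max(label8(branch_mask)) else 0L
  structure(list(
    cell_id = cell_id, skeleton_idx = which(skel),
    segments = lapply(segs, function(s)
      list(pixels = s$pixels, length_um = s$length_px * pixel_size_um)),
    total_length_um = total_px * pixel_size_um,
    n_branch_points = n_branch,
    n_endpoints = sum(skel & deg == 1L),
    dim = c(ny, nx)), class = "cell_skeleton")
}

#' @export
print.cell_skeleton <- function(x, ...) {
  cat(sprintf(
    "<cell_skeleton> cell %d: %.1f um over %d segments, %d branch pts, %d ends\n",
    x$cell_id, x$total_length_um, length(x$segments), x$n_branch_points,
    x$n_endpoints))
  invisible(x)
}

#' Per-cell ramification table
#'
#' Collects skeleton measures -- total process length, branch-point count,
#' endpoint count -- into one row per cell.
#'
#' @param skeletons A list of [skeletonize_cell()] results.
#' @return A data frame with columns `cell_id`, `total_length_um`,
#'   `n_branch_points`, `n_endpoints`.
#' @export
ramification_summary <- function(skeletons) {
  if (length(skeletons) == 0L)
    return(data.frame(cell_id = integer(0), total_length_um = numeric(0),
                      n_branch_points = integer(0), n_endpoints = integer(0)))
  do.call(rbind, lapply(skeletons, function(s) {
    stopifnot(inherits(s, "cell_skeleton"))
    data.frame(cell_id = s$cell_id, total_length_um = s$total_length_um,
               n_branch_points = s$n_branch_points,
               n_endpoints = s$n_endpoints)
  }))
}
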