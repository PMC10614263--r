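#' Segment individual microglia on a reference frame
#'
#' Connected components of the binarized reference frame above a minimum area
#' become cells. The soma of each cell is recovered by morphological opening
#' at a soma-scale radius (processes are thinner than the opening disk and
#' vanish; the cell body survives), keeping the largest opened component.
#' Cells touching the image border are flagged and excluded from morphometry.
#'
#' @param series A binary [projected_series()] (see [binarize()]).
#' @param reference_frame Frame index on which cells are delineated.
#' @param min_area_px Minimum component area, pixels (default 50).
#' @param soma_open_radius_um Radius of the opening structuring element,
#'   micrometres (default 2).
#' @return An object of class `cell_segmentation`: the label image (0 =
#'   background) and, per cell, its full and soma pixel sets, centroid and
#'   border flag.
#' @export
segment_cells <- function(series, reference_frame = 1L, min_area_px = 50L,
                          soma_open_radius_um = 2) {
  stopifnot(inherits(series, "projected_series"))
  if (!series$binary)
    stop("`series` must be binarized first (see binarize())", call. = FALSE)
  Tn <- n_frames(series)
  if (reference_frame < 1L || reference_frame > Tn)
    stop("`reference_frame` out of range", call. = FALSE)
  mask <- get_frame(series, reference_frame) > 0
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- EBImage::bwlabel(mask * 1.0)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  if (length(keep) == 0L) {
    warning("no components above `min_area_px`; empty segmentation")
    return(structure(list(label_image = matrix(0L, ny, nx), cells = list(),
                          pixel_size_um = series$pixel_size_um,
                          reference_frame = reference_frame,
                          soma_open_radius_um = soma_open_radius_um),
                     class = "cell_segmentation"))
  }
  open_r_px <- soma_open_radius_um / series$pixel_size_um
  brush <- disc_brush(open_r_px)
  label_image <- matrix(0L, ny, nx)
  cells <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    idx <- which(lab == keep[i])
    label_image[idx] <- i
    yy <- ((idx - 1L) %% ny) + 1L
    xx <- ((idx - 1L) %/% ny) + 1L
    touches <- any(yy == 1L | yy == ny | xx == 1L | xx == nx)
    cm <- matrix(FALSE, ny, nx); cm[idx] <- TRUE
    opened <- EBImage::opening(cm * 1.0, brush) > 0.5
    soma_idx <- integer(0)
    if (any(opened)) {
      slab <- EBImage::bwlabel(opened * 1.0)
      ssz <- tabulate(slab[slab > 0])
      soma_idx <- which(slab == which.max(ssz))
    }
    cells[[i]] <- list(cell_id = i, full_idx = idx, soma_idx = soma_idx,
                       touches_border = touches,
                       centroid = c(mean(yy), mean(xx)),
                       area_px = length(idx))
  }
  structure(list(label_image = label_image, cells = cells,
                 pixel_size_um = series$pixel_size_um,
                 reference_frame = reference_frame,
                 soma_open_radius_um = soma_open_radius_um),
            class = "cell_segmentation")
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat(sprintf("<cell_segmentation> %d cells on frame %d (%d border-touching)\n",
              length(x$cells), x$reference_frame,
              sum(vapply(x$cells, `[[`, logical(1), "touches_border"))))
  invisible(x)
}

get_cell <- function(seg, cell_id) {
  if (cell_id < 1L || cell_id > length(seg$cells))
    stop(sprintf("no cell with id %d", cell_id), call. = FALSE)
  seg$cells[[cell_id]]
}

mask_from_idx <- function(idx, ny, nx) {
  m <- matrix(FALSE, ny, nx)
  m[idx] <- TRUE
  m
}

# boundary length of a binary mask: marching-squares contour at level 0.5,
# vertices smoothed with a circular 5-point running mean to remove the
# pixel-staircase bias (raw marching squares overestimates a disk by 6-9%)
contour_perimeter_px <- function(mask, smooth_k = 5L) {
  if (!any(mask)) return(0)
  # pad so boundary cells produce closed contours
  ny <- nrow(mask); nx <- ncol(mask)
  z <- matrix(0, ny + 2L, nx + 2L)
  z[2:(ny + 1L), 2:(nx + 1L)] <- mask + 0
  cl <- grDevices::contourLines(x = seq_len(ny + 2L), y = seq_len(nx + 2L),
                                z = z, levels = 0.5)
  if (length(cl) == 0L) return(0)
  lens <- vapply(cl, function(co) {
    x <- co$x; y <- co$y
    nv <- length(x)
    closed <- abs(x[1] - x[nv]) < 1e-9 && abs(y[1] - y[nv]) < 1e-9
    if (closed && nv > 1L) { x <- x[-nv]; y <- y[-nv]; nv <- nv - 1L }
    if (nv >= smooth_k && closed) {
      half <- smooth_k %/% 2L
      idx <- outer(seq_len(nv), -half:half,
                   function(i, j) ((i + j - 1L) %% nv) + 1L)
      x <- rowMeans(matrix(x[idx], nv))
      y <- rowMeans(matrix(y[idx], nv))
    }
    sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  }, numeric(1))
  max(lens)
}

#' Soma perimeter of a segmented cell
#'
#' Contour length of the soma mask boundary (smoothed marching-squares
#' contour) scaled by the pixel size. Border-touching cells are refused: part
#' of their boundary is the image edge, not the cell.
#'
#' @param seg A [segment_cells()] result.
#' @param cell_id Cell label.
#' @param pixel_size_um Micrometres per pixel (default: taken from `seg`).
#' @return Perimeter in micrometres.
#' @export
measure_soma_perimeter <- function(seg, cell_id,
                                   pixel_size_um = seg$pixel_size_um) {
  stopifnot(inherits(seg, "cell_segmentation"))
  cl <- get_cell(seg, cell_id)
  if (cl$touches_border)
    stop(sprintf("cell %d touches the image border; perimeter not measured",
                 cell_id), call. = FALSE)
  ny <- nrow(seg$label_image); nx <- ncol(seg$label_image)
  contour_perimeter_px(mask_from_idx(cl$soma_idx, ny, nx)) * pixel_size_um
}

#' Phagocytic-cup area of a segmented cell
#'
#' Detects cup candidates as enclosed background cavities at process
#' terminals: the morphological closing of the cell mask minus the mask
#' itself. Candidates overlapping the (dilated) soma core or touching the
#' image border are discarded -- a phagocytic cup sits at a process terminal,
#' away from the cell body. The largest remaining cavity's area is returned;
#' `NA` (a valid result) when no candidate reaches the minimum area.
#'
#' @param seg A [segment_cells()] result.
#' @param cell_id Cell label.
#' @param close_radius_um Radius of the closing structuring element,
#'   micrometres (default 1.5; must exceed half the cup's mouth opening for
#'   the cavity to be enclosed).
#' @param min_cup_px Minimum cavity area in pixels (default 5).
#' @param pixel_size_um Micrometres per pixel (default: from `seg`).
#' @return Cup area in square micrometres, or `NA_real_` if none detected.
#' @export
measure_phagocytic_cup <- function(seg, cell_id, close_radius_um = 1.5,
                                   min_cup_px = 5L,
                                   pixel_size_um = seg$pixel_size_um) {
  stopifnot(inherits(seg, "cell_segmentation"))
  cl <- get_cell(seg, cell_id)
  ny <- nrow(seg$label_image); nx <- ncol(seg$label_image)
  mask <- mask_from_idx(cl$full_idx, ny, nx)
  brush <- disc_brush(close_radius_um / pixel_size_um)
  closed <- EBImage::closing(mask * 1.0, brush) > 0.5
  cav <- closed & !mask
  if (!any(cav)) return(NA_real_)
  lab <- EBImage::bwlabel(cav * 1.0)
  soma_excl <- EBImage::dilate(mask_from_idx(cl$soma_idx, ny, nx) * 1.0,
                               box3()) > 0.5
  best <- 0L
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k)
    if (length(idx) < min_cup_px) next
    if (any(soma_excl[idx])) next
    yy <- ((idx - 1L) %% ny) + 1L
    xx <- ((idx - 1L) %/% ny) + 1L
    if (any(yy == 1L | yy == ny | xx == 1L | xx == nx)) next
    if (length(idx) > best) best <- length(idx)
  }
  if (best == 0L) return(NA_real_)
  best * pixel_size_um^2
}
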