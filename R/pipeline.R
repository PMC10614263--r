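#' Full pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with its default.
#' Physical quantities are expressed in physical units (seconds,
#' micrometres); frame-based thresholds are derived internally via
#' [stability_threshold_frames()], so a configuration survives acquisition
#' changes. Defaults mirror the per-stage defaults.
#'
#' @param seed Master seed; per-animal simulation seeds derive from it.
#' @param outdir Run directory for all artifacts.
#' @param simulate Simulate input stacks (`TRUE`) or read TIFFs from
#'   `input_paths` (`FALSE`).
#' @param input_paths Named list: group -> character vector of stack paths
#'   (one per animal); used when `simulate = FALSE`.
#' @param groups Named list: group -> list of [sim_config()] overrides for
#'   that group (e.g. `stable_fraction`). Group names become group labels.
#' @param n_animals Animals (stacks) per group when simulating.
#' @param sim List of [sim_config()] overrides shared by all groups.
#' @param z_range Optional projection slab in micrometres (see
#'   [max_project()]).
#' @param threshold_method,fixed_threshold Binarization settings (see
#'   [binarize()]).
#' @param min_persistence_s Persistence criterion in seconds (default 180).
#' @param overlap_fraction,dilate_px,min_event_px Motility parameters (see
#'   [detect_extensions()] and [classify_stability()]).
#' @param min_cell_area_px,soma_open_radius_um Segmentation parameters.
#' @param cup_close_radius_um,min_cup_px Phagocytic-cup parameters.
#' @param prune_spur_px Skeleton spur pruning (see [skeletonize_cell()]).
#' @param per_animal Also run comparisons on per-animal means.
#' @param var_equal Pooled-variance t-test for 2-group comparisons.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       outdir = "microglia_run",
                       simulate = TRUE,
                       input_paths = NULL,
                       groups = list(
                         healthy = list(stable_fraction = 0.8),
                         cp_saline = list(stable_fraction = 0.35),
                         cp_d2pmpa = list(stable_fraction = 0.75)),
                       n_animals = 2L,
                       sim = list(),
                       z_range = NULL,
                       threshold_method = "otsu",
                       fixed_threshold = NULL,
                       min_persistence_s = 180,
                       overlap_fraction = 0.5,
                       dilate_px = 1L,
                       min_event_px = 4L,
                       min_cell_area_px = 50L,
                       soma_open_radius_um = 2,
                       cup_close_radius_um = 1.5,
                       min_cup_px = 5L,
                       prune_spur_px = 2L,
                       per_animal = FALSE,
                       var_equal = TRUE) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips losslessly: `read_run_config(write_run_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Preprocess a raw stack into a registered, binarized series
#'
#' Applies, in order: maximum-intensity z-projection, drift correction,
#' photobleach correction, and single-threshold binarization.
#'
#' @param stack A [timelapse_stack()].
#' @param config A [run_config()].
#' @return A binary [projected_series()] with full provenance.
#' @export
preprocess_stack <- function(stack, config = run_config()) {
  series <- max_project(stack, z_range = config$z_range)
  series <- correct_drift(series)
  series <- correct_bleach(series)
  binarize(series, method = config$threshold_method,
           threshold = config$fixed_threshold)
}

#' Analyze one binarized series: segmentation, motility, morphometry
#'
#' @param series A binary [projected_series()] (see [preprocess_stack()]).
#' @param config A [run_config()].
#' @return A list: `cells` (per-cell data frame of all endpoints), `events`
#'   (classified `extension_events`), `seg` (the segmentation).
#' @export
analyze_series <- function(series, config = run_config()) {
  seg <- segment_cells(series, reference_frame = 1L,
                       min_area_px = config$min_cell_area_px,
                       soma_open_radius_um = config$soma_open_radius_um)
  thr <- stability_threshold_frames(series$frame_interval_s,
                                    config$min_persistence_s)
  ev <- detect_extensions(series, seg, min_event_px = config$min_event_px)
  ev <- classify_stability(ev, series, stability_threshold_frames = thr,
                           overlap_fraction = config$overlap_fraction,
                           dilate_px = config$dilate_px)
  n_cells <- length(seg$cells)
  si <- stability_index(ev, per_cell = TRUE,
                        cell_ids = seq_len(n_cells))
  rows <- lapply(seq_len(n_cells), function(cid) {
    cl <- seg$cells[[cid]]
    r <- data.frame(cell_id = cid,
                    touches_border = cl$touches_border,
                    n_events = si$n_events[si$cell_id == cid],
                    n_stable = si$n_stable[si$cell_id == cid],
                    stability_index = si$stability_index[si$cell_id == cid],
                    soma_perimeter_um = NA_real_, cup_area_um2 = NA_real_,
                    total_process_length_um = NA_real_,
                    n_branch_points = NA_integer_, n_endpoints = NA_integer_)
    if (!cl$touches_border) {
      r$soma_perimeter_um <- measure_soma_perimeter(seg, cid)
      r$cup_area_um2 <- measure_phagocytic_cup(
        seg, cid, close_radius_um = config$cup_close_radius_um,
        min_cup_px = config$min_cup_px)
      sk <- skeletonize_cell(seg, cid, prune_spur_px = config$prune_spur_px)
      r$total_process_length_um <- sk$total_length_um
      r$n_branch_points <- sk$n_branch_points
      r$n_endpoints <- sk$n_endpoints
    }
    r
  })
  cells <- if (length(rows)) do.call(rbind, rows) else data.frame()
  list(cells = cells, events = ev, seg = seg)
}

#' Run the full pipeline: simulate/load, preprocess, analyze, report
#'
#' Executes preprocessing, segmentation, motility scoring, morphometry and
#' group statistics for every animal of every group, then writes per-cell
#' endpoint tables (stability index, soma perimeter, phagocytic-cup area,
#' process length), comparison statistics and run metadata under
#' `config$outdir`. Identical config + seed reproduce byte-identical CSVs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `tables` (named [group_table()]s),
#'   `comparisons` and `outdir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  groups <- names(config$groups)
  if (is.null(groups) || length(groups) == 0L)
    stop("`config$groups` must be a named list", call. = FALSE)
  if (!config$simulate) {
    if (is.null(config$input_paths))
      stop("simulate = FALSE requires `input_paths`", call. = FALSE)
    missing <- unlist(lapply(config$input_paths, function(p)
      p[!file.exists(p)]))
    if (length(missing))
      stop(sprintf("input stack(s) not found: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  all_cells <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n_an <- if (config$simulate) config$n_animals else
      length(config$input_paths[[g]])
    for (a in seq_len(n_an)) {
      if (config$simulate) {
        overrides <- c(config$sim, config$groups[[g]])
        overrides <- overrides[!duplicated(names(overrides),
                                           fromLast = TRUE)]
        overrides$seed <- config$seed + 1000L * gi + a
        cfg <- do.call(sim_config, overrides)
        stack <- simulate_timelapse(cfg)$stack
      } else {
        stack <- read_stack(config$input_paths[[g]][a])
      }
      series <- preprocess_stack(stack, config)
      res <- analyze_series(series, config)
      if (nrow(res$cells)) {
        res$cells <- cbind(data.frame(group = g,
                                      animal_id = sprintf("%s_%d", g, a)),
                           res$cells)
        all_cells[[length(all_cells) + 1L]] <- res$cells
      }
    }
  }
  cells <- if (length(all_cells)) do.call(rbind, all_cells) else
    data.frame()
  endpoints <- c(stability_index = "ratio", soma_perimeter_um = "um",
                 cup_area_um2 = "um2", total_process_length_um = "um")
  tables <- list()
  comparisons <- list()
  for (ep in names(endpoints)) {
    if (!nrow(cells)) break
    tab <- suppressMessages(group_table(
      cells$group, cells$animal_id, cells$cell_id, cells[[ep]],
      measurement = ep, units = endpoints[[ep]]))
    if (!nrow(tab)) next
    tables[[ep]] <- tab
    cmp <- tryCatch(
      compare_groups(tab, var_equal = config$var_equal,
                     per_animal = config$per_animal),
      error = function(e) NULL)
    if (!is.null(cmp)) comparisons[[ep]] <- cmp
  }
  build_report(tables, comparisons, config$outdir,
               config = unclass(config), seed = config$seed)
  if (nrow(cells))
    write.csv(cells, file.path(config$outdir, "cells.csv"),
              row.names = FALSE)
  invisible(list(tables = tables, comparisons = comparisons, cells = cells,
                 outdir = config$outdir))
}
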