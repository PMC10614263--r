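# microMotility

Quantitative analysis of **microglial process motility and morphology** from
fluorescence time-lapse imaging of live brain slices.

Microglia -- the resident immune cells of the CNS -- constantly extend and
retract fine processes to surveil their surroundings. Neuroinflammation
changes this behaviour: newly formed process extensions fail to hold their
position, somata enlarge, phagocytic cups grow, and ramification changes.
`microMotility` turns a raw 4D confocal stack (frames x z x y x x, with
pixel size and frame interval) into the standard readouts of that
phenotype, per cell and per treatment group.

## The core statistic

For a registered, binarized projection, a **process-extension event** at
frame *t* is a connected set of pixels present at *t* but absent at *t-1*
that grows out of existing structure. An event is **stable** if it holds
its position for at least 3 minutes -- `ceiling(180 / frame_interval_s)`
consecutive frames from its onset (3 frames at 1 frame/min). The
**stability index** is

    SI = (# stable extensions) / (# all extensions)  in [0, 1]

Lower SI means more restless, less stable processes. Zero-event cells get
an *undefined* index, excluded (with a logged count) from statistics.

Around the index, the package provides the full pipeline:

| Stage | Functions |
| --- | --- |
| Synthetic ground truth | `sim_config()`, `simulate_timelapse()`, `make_toy_binary_series()`, `apply_artifacts()` |
| Preprocessing | `max_project()`, `correct_drift()`, `correct_bleach()`, `binarize()` |
| Segmentation & soma/cup | `segment_cells()`, `measure_soma_perimeter()`, `measure_phagocytic_cup()` |
| Motility | `detect_extensions()`, `classify_stability()`, `stability_index()`, `stability_threshold_frames()` |
| Ramification | `skeletonize_cell()`, `ramification_summary()` |
| Statistics & reports | `summarize_groups()`, `compare_groups()`, `build_report()` |
| Orchestration | `run_config()`, `run_pipeline()`, plus `inst/scripts/microglia_pipeline.R` |

The simulator is first-class: it renders disk-soma cells with branched
processes, spawns extensions with known stability labels, then corrupts the
render with PSF blur, stage drift, photobleaching and shot noise -- so every
downstream number can be checked against ground truth. See the methods
vignette (`vignettes/microglia-motility-methods.Rmd`) for the model,
parameter defaults, and design rationale.

## Worked example

Simulate a CP-like field (restless microglia, true stable fraction 0.3)
with realistic artifacts, preprocess, and score it:

```r
library(microMotility)

cfg <- sim_config(image_size = 384L, n_z = 5L, n_cells = 4L,
                  n_primary_processes = 6L, extension_prob = 0.4,
                  stable_fraction = 0.3, noise_scale = 0.01,
                  bleach_rate = 0.05, drift_px_per_frame = c(1, 0),
                  seed = 42L)
sim <- simulate_timelapse(cfg)
sim$truth
#> <ground_truth> 4 cells, 70 events (21 stable), true SI = 0.300

series <- preprocess_stack(sim$stack, run_config())
series
#> <projected_series (binary)> 10 frames x 384 x 384 px | 0.273 um/px |
#>   steps: max_project -> correct_drift -> correct_bleach -> binarize

res <- analyze_series(series, run_config())
stability_index(res$events, per_cell = FALSE)$stability_index
#> [1] 0.3333333        # vs. ground truth 0.300

res$cells[, c("cell_id", "n_events", "stability_index",
              "soma_perimeter_um", "total_process_length_um")]
#>   cell_id n_events stability_index soma_perimeter_um total_process_length_um
#> 1       1       19       0.2631579          25.65623                88.97006
#> 2       2       19       0.3157895          25.51189                74.64472
#> 3       3       21       0.4285714          25.62315                85.62345
#> 4       4       16       0.3125000          25.55008                72.89771
```

The recovered pooled index (0.333) sits within sampling error of the
simulated truth (0.300); soma perimeters cluster near the analytic
2*pi*4 um = 25.1 um of the rendered somata. A full multi-group study --
simulate groups with different stable fractions, compare with ANOVA/Tukey,
write tidy CSVs -- is one call:

```r
res <- run_pipeline(run_config(seed = 1, outdir = "my_run"))
res$comparisons$stability_index   # per-endpoint group comparison
```

which writes `stability_index.csv`, `soma_perimeter_um.csv`,
`cup_area_um2.csv`, `total_process_length_um.csv`, `comparisons.csv`,
`tukey.csv`, `cells.csv` and `run_metadata.json` under `my_run/`.

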