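---
title: "Quantifying microglial process motility: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial process motility: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement

Microglia in healthy tissue continuously extend and retract fine processes
to surveil their surroundings. Under inflammatory activation this behaviour
changes: processes become restless, newly formed extensions fail to hold
their position, somata enlarge, and phagocytic cups grow. This package
quantifies those phenotypes from confocal time-lapse stacks of
lectin-labeled microglia in acute brain slices, imaged typically at one
frame per minute for ten minutes, 512 x 512 px over a 130-150 um field,
with z-stacks at 1-2 um spacing spanning 25-35 um of tissue.

The central statistic is the **stability index**. For a registered,
binarized 2D+time series, a *process-extension event* at frame $t$ is an
8-connected component of pixels present at $t$ but absent at $t-1$ that
grows out of existing structure. An event is *stable* if it holds its
position for at least 3 minutes, i.e. for
$\lceil 180\,\mathrm{s} / \Delta t \rceil$ consecutive frames counted from
its onset inclusively (3 frames at $\Delta t = 60$ s, the "series of three
images" window). The index is

$$\mathrm{SI} \;=\; \frac{\#\,\text{stable extensions}}{\#\,\text{all extensions}} \in [0,1],$$

computed per cell or pooled over the field; a cell with zero events has an
*undefined* index and is excluded from group statistics (with a logged
count), never coerced to 0 or 1.

"Holds its position" needs an operational definition on noisy masks. Exact
pixel-set equality would misclassify under 1-px breathing of the
binarization boundary, so persistence at frame $t$ requires that at least
`overlap_fraction` (default 0.5) of the *onset footprint* is occupied in
frame $t$ after dilating the frame mask by 1 px. Both knobs are exposed
(`overlap_fraction`, `dilate_px`); the defaults are the package's own
declared convention, since no exact overlap rule is recoverable from prior
art. Retractions are not scored: the index is defined on extensions only.
Events smaller than `min_event_px = 4` px are discarded (single-pixel shot
noise must not count as an extension), and events are assigned to the
nearest segmented cell; components touching no existing structure in the
previous frame are discarded as noise.

## Preprocessing

A raw stack is reduced to the scored series in four fixed steps:

1. **Maximum-intensity z-projection** over a selectable slab (in um).
2. **Drift correction**: each frame is registered to frame 1 by
   integer-pixel translation estimated with phase correlation. Integer
   shifts, not subpixel: interpolation would smear binary masks, and the
   analysis is pixel-presence-based. Registering to frame 1 rather than
   frame-to-frame prevents accumulation of estimation error. Estimated
   shifts are recorded in the series provenance.
3. **Photobleach correction**: frame $t$ is rescaled by
   $\bar I_1 / \bar I_t$, which makes the frame-mean intensity exactly
   constant. An exponential model is deliberately not fitted: ratio
   normalization is assumption-free and exact for any monotone decay.
4. **Binarization**: a single Otsu threshold computed on frame 1 is applied
   to all frames (or a user-fixed threshold). A per-frame threshold would
   jitter, creating spurious extension/retraction events at the boundary of
   every object -- fatal to the stability index. Bleach correction before
   thresholding is what makes the single threshold valid across frames.

All operations carry the physical calibration (`pixel_size_um`,
`frame_interval_s`) unchanged, and append their parameters to an ordered
provenance record written alongside every exported series.

## Morphometry

* **Soma**: morphological opening of each segmented cell at a soma-scale
  radius (default 2 um) -- processes are thinner than the opening disk and
  vanish, the cell body survives; the largest opened component is the soma.
* **Soma perimeter**: marching-squares contour of the soma mask, with the
  contour polygon smoothed by a 5-point circular running mean before
  summing segment lengths. The smoothing matters: the raw marching-squares
  polygon overestimates a digital disk's perimeter by 6-9% from staircase
  bias; after smoothing the error is below 1%. Scaled by `pixel_size_um`
  (exactly linear in calibration).
* **Phagocytic cup**: cup candidates are enclosed background cavities
  revealed by morphological closing of the cell mask (closing radius
  default 1.5 um -- it must exceed half the cup's mouth width), minus the
  mask. A cavity is a cup candidate if it is disjoint from the dilated soma
  core and does not touch the image border; the largest candidate above
  `min_cup_px` is reported in um^2, and *absent* (`NA`) is a valid result
  for cells without cups. A cup is a closed or nearly closed loop, so its
  skeleton carries a cycle rather than an endpoint; that is why candidacy
  is defined by position relative to the soma rather than by adjacency to a
  skeleton endpoint. For real data where cups are delineated by hand, the
  measured area of a manual ROI can be substituted -- the automated
  geometric surrogate is the tested default.
* **Ramification**: the cell mask minus the soma is thinned to a 1-px
  skeleton (Zhang-Suen; no installed package provides 2D topology-preserving
  thinning, so it is implemented here), spurs shorter than 2 px are pruned,
  and the skeleton is decomposed into polylines between branch points
  (>= 3 graph neighbors) and endpoints (exactly 1). Two numerical details
  are load-bearing. First, thinning leaves staircase triangles on diagonal
  runs; treating every 8-adjacency as an edge walks each triangle as three
  segments and overcounts length by tens of percent. A diagonal edge is
  therefore dropped whenever either of its corner axial pixels is itself on
  the skeleton. Second, thinning erodes free line ends by roughly the
  stroke half-width, so each endpoint receives a cap equal to the local
  mask radius (from a distance transform). With both corrections a 50-px
  bar and a 45-degree diagonal bar are measured within 5%, and path
  coordinates are smoothed (3-point running mean on interior vertices)
  before Euclidean summation to remove digital-path bias. Branch points are
  counted as 8-connected clusters of high-degree pixels, since a thick
  crossing thins to a small cluster rather than a single pixel.

## Group statistics

Summaries are mean +/- SEM (SEM = sd/sqrt(n)). Two groups are compared with
a two-sided unpaired t-test (pooled variance by default, Welch by flag);
three or more with one-way ANOVA followed by all-pairs Tukey HSD. The unit
of analysis is the cell; animal ids are carried so the same comparisons can
be run on per-animal means (`per_animal = TRUE`), since pooled cells from
few animals are not independent -- both analyses are emitted and labeled.
The calibration generator `simulate_si_table()` draws per-cell indices as
binomial fractions (`stable / n_events` with Poisson-distributed event
counts, mean 10), reproducing the discreteness and heteroscedasticity of
real per-cell indices; under the null its ANOVA rejection rate at
alpha = 0.05 is verified to sit in [0.03, 0.07], and a 3-group design with
true indices (0.8, 0.4, 0.4) and 8 cells/group has power > 0.8.

## The simulator

`simulate_timelapse()` renders ground-truthed stacks so that every stage of
the pipeline is testable without real data. Geometry: disk somata (radius
4 um) placed on a jittered grid, 5 piecewise-linear processes per cell
(12 um, 3 segments with angular jitter, one optional side branch at
probability 0.3), rendered at 0.8 um stroke width. Kinetics: at each frame
in the spawn window, each active tip sprouts a new 3-um terminal extension
with probability `extension_prob`; the extension is stable with probability
`stable_fraction`. Stable extensions persist to the final frame and advance
the tip (up to three growth steps per tip); unstable ones retract after
`unstable_lifetime_frames` (default 1). Image formation follows the fixed
order geometry -> Gaussian PSF (sigma 0.3 um) -> stage drift (integer px,
cumulative) -> exponential bleaching -> Poisson shot noise, with drifted-in
borders filled at the background level; one explicitly seeded RNG stream
makes identical configs bit-identical.

Ground truth records every event (onset, footprint, lifetime, label), the
per-frame true process length, the true per-cell and pooled SI, the applied
drift vectors and bleach factors, and the clean projected geometry. Three
bookkeeping rules keep truth in one-to-one correspondence with what a
frame-difference detector can see: event onsets are confined to frames
`2 .. n_frames - 2` (so a "stable" label always has three observable
frames -- otherwise truth labels and the 3-frame rule disagree on
right-censored events); a footprint must be new relative to the previous
frame's mask, not just to current occupancy (a pixel vacated by a transient
this frame is not "new" to the detector); and a spawn is skipped if its
footprint is not a single 8-connected blob or abuts another footprint born
the same frame (which would merge on detection). With these rules the
detector recovers the exact ground-truth event count on noiseless geometry,
which the tests assert.

What the simulator does *not* emulate: tissue background structure
(vasculature, neuropil), the activation gradient near the cut slice
surface, labeling heterogeneity, focal drift in z, and cell movement.
Passing tests therefore demonstrate correctness of the *computation* under
controlled kinetics, not robustness to every property of real slices; on
real data the exposed thresholds (binarization method, `min_event_px`,
`overlap_fraction`) are the knobs to revisit. Background level is a free
parameter (default 0.02 of the cell amplitude) since labeling efficiency is
not specified by any source we emulate.

## Problem sizes and determinism

The test suite and the acceptance script run the simulator at a 384-px
field (~105 um) with 5 z-planes and 4 cells -- the package's chosen
validation size, large enough for >= 50 events per run with well-separated
cells -- and at smaller sizes for unit fixtures. The full-size defaults
(512 px, 15 planes) are what `sim_config()` ships with. All stochastic
stages draw from explicitly seeded streams; re-running any pipeline with
the same configuration and seed reproduces byte-identical CSV outputs,
which both the tests and the acceptance script verify.

## Known limitations

* Registration is translation-only and integer-pixel; rotation or nonrigid
  tissue deformation is out of scope.
* The stability index inherits the binarization: systematically dim or
  blebby processes can drop below a frame-1 Otsu threshold and depress
  event counts. The fixed-threshold mode exists for such data.
* Phagocytic-cup detection is a geometric surrogate for a manual call; cups
  whose mouth exceeds twice the closing radius stay open and are missed.
* Skeleton length on heavily overlapping or self-crossing processes counts
  merged geometry once, so per-cell recovery is validated at the field
  level (within 10%) rather than per cell.
* The spec's per-event persistence rule is evaluated on the onset
  footprint; an extension that slides while keeping contact is scored by
  its original position, matching the "same position" definition.
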