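Package: microMotility
Title: Microglial Process Motility and Morphometry from Fluorescence Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies microglial process dynamics and morphology from 4D
    fluorescence time-lapse stacks of live brain slices. Provides
    maximum-intensity z-projection, integer-pixel drift correction by phase
    correlation, photobleach normalization, single-threshold binarization,
    per-cell instance segmentation, detection of new process-extension events
    and their frame-to-frame persistence (the stability index), soma-perimeter
    and phagocytic-cup morphometry, skeleton-based ramification measures, and
    a group-statistics layer (mean +/- SEM, one-way ANOVA with Tukey HSD,
    unpaired t-tests). A ground-truthed synthetic time-lapse simulator with
    controllable extension/retraction kinetics, stage drift, photobleaching
    and shot noise supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
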