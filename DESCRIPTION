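Package: caltrace
Title: Calcium Imaging Analysis: Cell Segmentation, Spike Detection and
    Network Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable pipeline for time-lapse calcium-imaging movies of
    neuronal cultures. Detects cell bodies (regions of interest) on a reference
    frame with a difference-of-Gaussians blob filter, extracts per-cell
    brightness traces, flags calcium spikes with an influence-limited
    sliding-window z-score on the brightness rate of change, computes lagged
    Pearson cross-correlations between cells, and reconstructs a directed
    communication network constrained by physiologically plausible connection
    length and response delay. Includes ground-truth-based benchmarking of
    segmentations and spike trains, and a seeded synthetic-movie generator so
    every stage can be validated without external data. All tabular results are
    tibbles; fitted networks support tidy() and glance(); ggplot2 helpers draw
    traces, correlation matrices, activity maps and the reconstructed network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
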