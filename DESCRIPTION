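Package: routecells
Title: Route Versus Goal Coding Analysis for Hippocampal Place Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for deciding whether hippocampal place cells
    on a multi-route maze encode specific routes or intended goals.
    Provides occupancy-normalised Gaussian-kernel firing rate maps with
    spatial information content, spike-cluster quality metrics (isolation
    distance, L-ratio, signal-to-noise), trial-wise differential-firing
    tests with covariate control (ranked ANCOVA, permutation F-test, and a
    Poisson GLM) with route/goal pattern classification, leave-one-out
    population-vector decoding with cosine similarity and shuffle nulls,
    goal-box similarity analysis, and win-stay behavioural scoring. A
    synthetic-data generator emulates the maze task, trajectories,
    route- or goal-modulated spike trains, and spike-feature clouds with
    known ground truth, so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
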