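Package: ringgap
Title: Simulation and Analysis of Ring-Gap and Single-Gap Climbing Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An agent-based simulator and analysis pipeline for Drosophila
    gap-climbing behaviour. Simulates cohorts of flies exploring a circular
    arena with concentric water-filled ring-gaps under a parallax-perception
    decision model, and single-gap catwalk sessions under dark, clear and
    striped visibility. Computes the screen kinematic parameters from 1 Hz
    track tables (mean distance from centre, drowned flies per groove,
    walking activity), classifies lines into six screen categories via
    population quantile boundaries, and derives per-fly attempt, fall and
    crossing fractions with exact and approximate Wilcoxon rank-sum
    comparisons against controls. Includes a synthetic overhead-camera
    module that renders backlit frames and recovers tracks by blob
    detection and nearest-neighbour linking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
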