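Package: svpower
Title: Simulation-Based Experimental Design for Single-Cell Time-Course
    Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Monte-Carlo power analysis for detecting temporal
    protein-abundance trajectories from small numbers of destructively
    sampled single cells. Simulates linear-trend populations, interpolates
    sparse subsamples onto a pseudotime grid with a Gaussian kernel,
    classifies each subsample by the area between curves against true and
    null references, and summarises true-positive and false-positive rates
    across slope, variation and sample-size grids, generalised through the
    scale-free slope-to-variation (S/V) ratio. Includes an S/V estimator
    for real data, cutoff-retention simulation, replicate detection-rate
    arithmetic for budgeting cells across replicate time courses, and
    two-group fold-change and variation summaries of protein-by-cell
    abundance tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
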