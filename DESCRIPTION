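Package: qufish
Title: Per-Cell Transcript Profiling from QuPath smFISH Detection Exports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts QuPath detection-measurement exports from single-molecule
    FISH (smFISH/RNAScope) experiments into tidy per-cell transcript expression
    profiles, and analyses them: thresholded single- and multi-target abundance,
    co-expression (double-positive) cell quantification, positivity-threshold
    calibration against biologically impossible marker combinations, per-image
    differential statistics (Mann-Whitney), and spatial transcript-distribution
    plots with micrograph overlay. Ships a synthetic-tissue generator that emits
    QuPath-dialect exports with a tunable boundary-spillover artefact, so every
    pipeline stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
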