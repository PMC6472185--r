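Package: nanolane
Title: Lane-Level Normalization and Exploratory Analytics for NanoString
    nCounter Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses NanoString nCounter RCC lane files, computes the three
    standard per-lane quality-control flags (binding density, positive-control
    linearity, limit of detection), normalizes cartridges with
    negative-control background thresholding and geNorm-selected housekeeping
    scaling factors, filters genes by expression instability, builds z-scored
    hierarchically clustered heatmap matrices with clinically meaningful
    sample orderings, and infers directed gene regulatory networks with
    random-forest, extra-trees and gradient-boosting tree ensembles. Includes
    a synthetic cartridge simulator with known ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
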