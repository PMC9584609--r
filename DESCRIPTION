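Package: dccsmlm
Title: Oligomeric State of Membrane Proteins from Dual-Color
    Single-Molecule Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the oligomeric state (subunit stoichiometry) of
    plasma-membrane proteins from dual-color single-molecule localization
    microscopy (SMLM/PALM) data by the dual-color colocalization (DCC)
    strategy. Provides localization-table input/output, fiducial-bead drift
    correction, lateral chromatic aberration registration (global linear fit
    or regional grid), DBSCAN clustering of localizations into fluorophore
    clusters, pair-correlation analysis, background-corrected colocalization
    ratios, binomial detection models with an optional double-loss factor,
    grid fitting with bootstrap confidence intervals, Kolmogorov-Smirnov
    classification, and a ground-truth synthetic scene generator for
    validation.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
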