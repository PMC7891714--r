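Package: nirsload
Title: Multi-Distance fNIRS Workload Analysis with Synthetic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses high-density, multi-distance functional
    near-infrared spectroscopy (fNIRS) recordings of prefrontal cortex
    activity during skilled motor tasks. Provides a synthetic cohort
    generator with separation-dependent mixing of cerebral and superficial
    hemodynamics, modified Beer-Lambert law conversion, zero-phase
    band-pass filtering, windowed standard-deviation motion-artifact
    rejection, short-separation superficial signal regression, window-SD
    activation features, channel-wise group statistics with Bonferroni
    control and topographic interpolation, and linear support-vector-machine
    classification of task load and skill level with an
    incremental-feature accuracy curve and a selection-in-the-loop
    permutation null.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
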