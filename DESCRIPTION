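Package: shagcarpet
Title: Delay-Sorted Carpet Plots and Transit Times for BOLD fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Sorted Hemodynamic Arrival Graph (SHAG) carpet plots from
    4D BOLD fMRI data: estimates per-voxel signal-arrival delays (systemic
    low-frequency oscillation cross-correlation for resting state, gamma-variate
    time-to-peak for dynamic susceptibility contrast, end-tidal CO2
    cross-correlation for gas-challenge scans), orders voxel rows by delay,
    detects tilted intensity edges with a slope-detection algorithm, and
    converts edge slopes into transit times that quantify how fast a bolus or
    a systemic oscillation propagates through the brain. Includes synthetic
    phantom generators with known delays, a contrast-by-noise robustness grid
    for the detector, and a repetition-time sampling-error simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    RNifti,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
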