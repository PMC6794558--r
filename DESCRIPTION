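Package: gazeaoi
Title: Bottom-Up Areas of Interest for Eye-Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A bottom-up pipeline for screen-based eye-tracking studies: raw
    binocular gaze samples are fused into a cyclopean trace, fixations and
    saccades are classified with a per-trace adaptive velocity threshold,
    fixation-density centroids are located by mean-shift clustering, the
    screen is partitioned into a-posteriori areas of interest (AOI) by
    Voronoi tessellation around those centroids, and per-participant
    relative fixation durations (RFD) are exported as a long-format table
    for group statistics. Includes a seeded synthetic scanpath generator so
    every stage can be validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    ggplot2,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
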