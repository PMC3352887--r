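Package: flytrackr
Title: Video Tracking and Sleep/Locomotor Analysis for Drosophila Tube Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An image-subtraction centroid tracker and coordinate-analysis
    stack for long-term Drosophila sleep and locomotion phenotyping in
    65 mm glass tubes. Converts grayscale arena frames into 1 Hz coordinate
    records by reference-image subtraction and connected-component
    centroiding, scores per-second movement with thresholds expressed as
    fractions of the fly body length (FBL), emulates infrared-beam activity
    monitors with a virtual beam, applies the 5-minute immobility rule to
    derive sleep architecture (total sleep, episodes, latency, activity
    index), and computes distance, speed, population activity, and tube
    place-preference occupancy. Includes a seeded two-state circadian
    trajectory simulator and frame renderer for end-to-end validation, plus
    readers and writers for coordinate files and Trikinetics-style DAM
    monitor files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    stringr,
    generics,
    stats,
    utils,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
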