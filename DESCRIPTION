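Package: nestboxr
Title: Contact-Free Activity, Surface Temperature, and Respiration Analysis
    for Nest-Box Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline analysis stack for nest-box imager recordings of small
    hibernating rodents. Quantifies activity from passive-infrared motion event
    logs (binning, actograms, 24-hour integration, Pearson comparison against a
    reference sensor), converts low-resolution thermal-camera frames to surface
    body temperature via linear calibration and brightest-decile pixel
    averaging, and extracts respiratory rate from near-infrared video by
    centroid tracking of a followable feature and moving-window Fourier
    analysis. Includes seeded synthetic generators for all three data streams
    so every stage is testable with known ground truth, and a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
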