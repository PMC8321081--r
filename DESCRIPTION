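Package: phasetrack
Title: Fully-Automated Cell Tracking for Phase-Contrast Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for fully-automated tracking of slow-moving adherent cells
    in phase-contrast time-lapse sequences. Provides two segmentation backends
    (edge detection followed by region-based active-contour evolution, and
    temporal-mode background reconstruction with subtraction), a greedy
    global-minimum centroid linker with an interval-scaled distance threshold,
    trajectory assembly and duration filtering, directional-migration
    statistics with star-plot export, strict accuracy scoring against ground
    truth, a time-step-interval sweep, and an adaptive acquisition-interval
    controller. A ground-truthed synthetic phase-contrast time-lapse simulator
    of directed and random cell migration is included for calibration and
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
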