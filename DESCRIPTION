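Package: hiermotion
Title: Hierarchical Multimodal Human Activity Recognition with
    Watch-to-Skeleton Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising daily activities from a wrist-worn
    inertial sensor (3-axis accelerometer and gyroscope at 50 Hz) combined
    with skeleton tracks from an RGB-Depth camera (12 joints at 30 Hz).
    Implements normalized-cross-correlation binding of each skeleton track
    to the wrist sensor worn by the same person in multi-person scenes,
    motion-sensor and skeleton/edge feature extraction over six-second
    windows, an automatic greedy group-selection search that builds a
    two-layer hierarchical classifier, probabilistic fusion of the two
    layers, a motion-only fallback for subjects outside the camera view,
    confusion-matrix evaluation with leave-one-subject-out cross
    validation, and a synthetic multimodal scene generator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
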