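Package: infantmotion
Title: Markerless Movement Analysis of Infants from Single-Camera Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic analysis of infant spontaneous movements from
    single-camera video. Tracks the four end effectors (hands and feet) with a
    pyramidal Kanade-Lucas-Tomasi point tracker constrained to a head-length
    scaled search window, normalizes trajectories by head length, and extracts
    a battery of kinematic features (velocity, acceleration, inter-limb
    cross-correlation, area from moving average, mean-crossing periodicity)
    together with frame-differencing motion-image features (quantity and
    centroid of motion). Includes a synthetic supine-infant scene generator
    with ground truth for benchmarking, and inter-rater reliability statistics
    (zero-lag trajectory correlation, two-way random absolute-agreement
    intraclass correlation, z-axis contribution analysis).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    png,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
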