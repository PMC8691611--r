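Package: actimetr
Title: Epoch-Based Activity Metrics from Raw Triaxial Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes epoch-based activity signals from raw wrist-worn
    triaxial accelerometer recordings. Implements the six standard
    preprocessed dataset types (unfiltered and band-pass-filtered axial
    signals, vector magnitudes computed before or after filtering, and the
    gravity-normalized magnitude), seven activity metrics from the
    actigraphy literature (PIM, ZCM, TAT, MAD, ENMO, HFEN and the Activity
    Index) with an applicability matrix, SD-adaptive level-crossing
    thresholds with a cumulative threshold-sweep analysis, axial
    combination indicators (sum, sum of squares, VM3), and time- and
    frequency-domain correlation comparison of activity signals across
    subjects. A seeded synthetic wrist-motion generator makes the whole
    pipeline testable without external data, and a command-line interface
    ties the steps into reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
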