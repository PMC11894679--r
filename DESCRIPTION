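Package: msptdfast
Title: Multi-Scale Peak and Trough Detection of Heartbeats in the Photoplethysmogram
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects heartbeats in photoplethysmogram (PPG) signals using the
    multi-scale peak and trough detection family of algorithms (AMPD, MSPTD,
    MSPTDfast v.1 and v.2), which locate pulse peaks and onsets via a local
    maxima scalogram. Includes the surrounding beat-detection framework
    (windowing, band-pass filtering, fiducial tidying, mid-point extraction,
    flat-line exclusion), an evaluation suite (clock-drift alignment, tolerance
    beat matching, sensitivity/positive predictive value/F1, windowed heart-rate
    mean absolute percentage error, signal-to-noise-ratio stratification,
    rank-sum group comparison with Holm-Sidak correction), and a seeded
    synthetic PPG generator with analytic ground truth for testing detectors
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
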