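Package: hankelppg
Title: Motion-Artifact Removal and Heart-Rate Estimation for Wrist PPG via
    Hankel-Matrix SVD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Heart-rate estimation from motion-corrupted wrist
    photoplethysmography (PPG) recorded together with a 3-axis accelerometer.
    Implements a two-stage method: a rule-based per-window signal-quality check
    that labels each window with a binary Signal Quality Token (pulsatility,
    inter-beat-interval consistency, and per-cycle statistical gating), and
    motion-artifact removal by Hankel-matrix embedding and singular value
    decomposition, rejecting components whose time courses correlate with the
    acceleration channels, followed by spectral heart-rate estimation with
    temporal tracking. Includes an adaptive notch-filter variant for
    hand-movement artifacts, a seeded synthetic PPG+accelerometer generator
    with ground truth, readers for CSV and IEEE Signal Processing Cup 2015
    style MAT records, and agreement metrics (mean error, MAE, Pearson
    correlation, Bland-Altman limits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
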