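Package: tpear
Title: Gait Event Detection from Ear-Worn Inertial Measurement Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects initial-contact (IC) and terminal-contact (TC) gait
    events from ear-worn six-axis inertial measurement unit (IMU)
    recordings. Implements two detectors built on singular spectrum
    analysis (SSA) of the superior-inferior and mediolateral acceleration
    channels: a baseline detector that derives TC from the mediolateral
    signal, and TP-EAR, which derives both events from the
    superior-inferior signal and is therefore robust to lateral head
    movements. Includes trial ingestion with dropped-sample repair and
    data-quality exclusion rules, quaternion error-state attitude
    estimation for yaw-based turn segmentation, per-cycle stride, stance
    and swing times, a tolerance-window evaluation protocol (sensitivity,
    laterality accuracy, absolute and signed timing errors), and a
    synthetic gait-trial simulator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
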