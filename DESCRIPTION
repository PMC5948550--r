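Package: fallsense
Title: Kalman-Filter Fall Detection from Waist-Worn Triaxial Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Streaming threshold-based fall detector for waist-mounted triaxial
    accelerometer recordings (SisFall text dialect). Implements 25 Hz decimation
    with a 4th-order Butterworth low-pass stage, a 4-state identity-transition
    Kalman smoother with a sliding vertical-bias tracker, the non-linear fused
    feature J3 (windowed-max sum-vector magnitude times squared windowed-max
    standard-deviation magnitude), and a zero-crossing gait-periodicity veto
    that suppresses false alarms from periodic activities. Ships a seeded
    synthetic accelerometry generator, a stratified k-fold evaluation harness
    with sensitivity/specificity/balanced-accuracy and Cohen's kappa reporting,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
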