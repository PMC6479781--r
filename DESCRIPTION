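Package: kinectgait
Title: Markerless Gait Kinematics, Calibration and Measurement Agreement
Version: 0.1.0
Authors@R:
    person("Gait", "Lab", email = "gaitlab@example.org", role = c("aut", "cre"))
Description: Tools for validating depth-sensor ("Kinect-style") markerless gait
    analysis against marker-based optical motion capture. Computes lower-limb
    joint kinematics from both landmark streams using clinically conventional
    segment coordinate systems (Euler sequence flexion/adduction/rotation for
    the hip, vector angles for the reduced landmark set), performs gait-cycle
    segmentation and 101-point time normalization, calibrates the markerless
    kinematics with per-degree-of-freedom linear regression and a two-layer
    LSTM sequence model, and quantifies concurrent validity and inter-day
    reliability with RMSE, the coefficient of multiple correlation (Kadaba),
    normality-gated correlation, Bland-Altman limits of agreement, ICC(2,k)
    with confidence intervals, and the standard error of measurement. A
    synthetic gait generator with a parameterized distortion model replaces
    patient data so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
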