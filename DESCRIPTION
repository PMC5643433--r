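Package: icuvr
Title: Oculomotor and Vital-Sign Analysis for VR Stimulation Studies in
    Intensive Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis pipeline for head-mounted-display virtual
    reality stimulation studies in intensive-care settings: pupil detection
    and eyes-closed classification from grayscale eye-camera frames
    (Gaussian/median denoising, Canny edges, small-object removal, circular
    Hough transform), dispersion-based (I-DT) fixation and saccade parsing of
    60 Hz gaze traces with blink-gap handling, sliding-window oculomotor
    features (fixation duration, fixation rate, saccade amplitude,
    fixation/saccade ratio), two-minute median aggregation of vital signs
    onto a begin/middle/end analysis grid, a linear mixed-effects model
    ladder (random intercepts, uncorrelated and correlated random time
    slopes) with likelihood-ratio selection, Nakagawa marginal and
    conditional R-squared, Holm-adjusted rating effects, and one-sided
    midpoint t-tests for questionnaire scales. Includes synthetic-data
    generators that emulate the statistical structure of such studies, with
    full ground truth retained for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    lme4,
    Matrix,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    optparse
Config/testthat/edition: 3
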