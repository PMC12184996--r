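Package: facestress
Title: Automated Facial-Landmark Stress Scoring for Head-Fixed Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns per-frame facial-landmark trajectories of a head-fixed
    mouse (two ears, four eyelids, one nose, as exported by markerless
    pose-tracking software) into per-feature and aggregate stress scores on
    a 0-10 scale with a three-level status. Implements eyelid-aperture
    blink/squint classification, nose and ear activity indices over
    2-second windows, ear-asymmetry and ear-fold detection, freezing
    detection, weighted multi-feature aggregation with feature ablation,
    a streaming (live) evaluator, method-comparison statistics (profile
    normalization, Pearson correlation, Cohen's kappa, Monte Carlo
    identity-shuffle tests), and a synthetic session simulator with
    ground-truth event logs for end-to-end testing without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
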