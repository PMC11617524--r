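Package: standgaze
Title: Gaze and Kinematic Analysis of Assisted Sit-to-Stand Transfers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing wearable eye-tracking and optical motion-capture
    recordings of therapist-assisted sit-to-stand transfers. Provides a seeded
    synthetic-trial generator (marker trajectories, six-plate ground reaction
    forces, gaze streams), preprocessing (synchronisation, zero-phase Butterworth
    smoothing, marker gap interpolation), rigid-body kinematics (virtual ASIS
    reconstruction, weighted-segment whole-body centre of mass, trunk Cardan
    angles, seat-off and ankle dorsiflexion events), I-VT fixation detection with
    landmark-anchored areas of interest, the four standard AOI gaze metrics, and
    mixed-design ANOVA / pooled t-test reporting of group differences between
    expert and novice assistance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
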