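Package: povmotion
Title: Pose-Based Movement Indices and Hyperactivity Classification from
    Point-of-View Video Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies seated-child motor activity from 33-keypoint
    pose-landmark time series recorded by a teacher-worn point-of-view
    camera. Provides a synthetic cohort generator, landmark session
    input/output with validation, trajectory quality control (confidence
    gating, two-tier gap repair with linear interpolation and a
    constant-velocity Kalman fill, One Euro smoothing), composite-region
    kinematics with pelvis-rooted windowed displacement activity indices,
    rank-based group statistics with false-discovery-rate and domain-wise
    Bonferroni control, and nested stratified cross-validated
    classification of hyperactivity risk with permutation feature
    importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    ranger,
    rpart,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
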