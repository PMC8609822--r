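Package: hipclear
Title: Subject-Specific Modelling of Anterior Femoroacetabular Clearance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for predicting anterior femoroacetabular clearance (the
    beta angle) from subject-specific bone geometry and motion-capture hip
    kinematics. Provides 3D geometry primitives (least-squares sphere and
    axis fitting, plane slicing and projection), point-to-point iterative
    closest point registration, ISB pelvis and femur anatomical coordinate
    systems with Grood-Suntay hip angle decomposition, a radial-reslicing
    clearance model that reports per-plane and minimum beta angles, a
    marker-cluster motion-capture pipeline with standing calibration and
    posture matching, validation statistics (least-squares angle error,
    accuracy summaries, Pearson and intraclass correlation, threshold
    inclusion), and a parametric hip phantom generator with analytic
    clearance ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
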