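Package: spinedvc
Title: Digital Volume Correlation and Clinical Metric Prediction for the
    Lumbar Spine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Subset-based three-dimensional digital volume correlation (DVC)
    between paired MRI volumes of the lumbar spine, with downstream
    Green-Lagrange strain tensor mapping of intervertebral discs, vertebral
    body kinematics (translations, anterolisthesis, precision screening),
    landmark-based clinical measures of disc geometry and sagittal alignment
    (disc heights, Cobb segmental and lumbar lordosis, sacral angle,
    Pfirrmann consensus grading), and a statistics layer (VIF screening,
    backward multivariate regression, residual diagnostics, Hommel
    family-wise correction, inter-rater ICC). Includes an analytic speckle
    and spine phantom module with closed-form displacement and strain
    oracles so the whole pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    lmtest,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
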