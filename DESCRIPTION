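Package: grfimu
Title: Self-Supervised Pre-Training of IMU Transformers for Ground Reaction
    Force Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating three-axis ground reaction force (GRF) from
    wearable inertial measurement units (IMUs) with a patch-masked transformer.
    Includes synthetic IMU generation from rigid-segment kinematics, window
    segmentation and exclusion filtering, masked-patch self-supervised
    pre-training, two-step fine-tuning for GRF regression, subject-wise
    cross-validated evaluation with stance-phase metrics and spectrum analysis,
    and a synthetic gait/drop-landing data generator so the full pipeline runs
    without external datasets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
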