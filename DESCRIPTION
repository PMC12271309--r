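Package: segqa
Title: Technical Validation of Multi-Class Abdominal Tissue Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Accuracy, agreement and precision analysis for deep-learning
    fat and muscle segmentations of abdominal MRI. Provides overlap and
    surface-distance accuracy metrics (Dice, IoU, 95th-percentile Hausdorff
    distance, normalised surface Dice), STAPLE expectation-maximisation
    consensus over multiple raters, ensemble combination and
    largest-connected-component post-processing, test-retest repeatability
    statistics (within-subject coefficient of variation, intraclass
    correlation, asymmetric limits of agreement), a hierarchical Bayesian
    model of segmentation bias fitted by Hamiltonian Monte Carlo with
    Gelman-Rubin diagnostics, and repeatability-coefficient classification
    of longitudinal tissue-volume change. A synthetic abdominal phantom
    and cohort simulator supply fully specified test-bench inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    rjags,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
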