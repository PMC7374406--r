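Package: spinedst
Title: Dempster-Shafer Evidence Classification of Low Back Pain from
    Spinal Repositioning Errors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for objective classification of non-specific low back
    pain (NSLBP) subgroups from spinal repositioning-sense data.  Computes
    absolute, constant and variable repositioning errors from trial-level
    posture-matching records, extracts thoracic/lumbar curvature and pelvic
    tilt angles from sagittal-plane spinal-curve and pelvis marker data, and
    classifies subjects into clinical subgroups (flexion pattern, active
    extension pattern, passive extension pattern, pain-free) with a two-class
    Dempster-Shafer belief-function classifier: per-variable sigmoid
    confidence factors, linear mapping to bodies of evidence with tunable
    uncertainty bounds, Dempster's rule of combination, and simplex-plot
    visualisation.  Includes leave-one-out cross-validation, single-variable
    discriminative ranking, a synthetic-cohort generator parameterised by
    published group means and standard deviations, and a small command-line
    driver for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
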