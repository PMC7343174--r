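Package: graspid
Title: Subject-Specific Grasping Pattern Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing the subject-specificity of human grasping
    patterns from optical motion capture and fingertip force recordings.
    Provides a synthetic multi-subject grasp-trial generator, marker-based
    joint-angle extraction, spring-platform force-sensor calibration,
    phase segmentation and time normalization into fixed-length feature
    matrices, t-SNE embedding with inverse-square-distance weighted
    k-nearest-neighbour classification under k-fold cross-validation, and
    an exhaustive feature-subset sensitivity analysis based on noise
    substitution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
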