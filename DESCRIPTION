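Package: gaitpattern
Title: Movement-Pattern Analysis of Running Gait Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Pattern-recognition pipeline for time-normalized sagittal-plane
    joint-angle waveforms recorded over single running cycles. Builds a
    trials-by-variables feature matrix from nine angle waveforms (201 time
    points each), standardizes it per angle block, and analyses it with
    K-means clustering under silhouette-based model selection, cluster
    loading rates, pairwise leave-one-out linear support-vector
    classification with exact binomial significance, discriminant
    back-projection to angle space with a 2-SD variable-selection rule, and
    a pooled-standard-deviation left/right symmetry index with a
    nonparametric test battery (Kruskal-Wallis, Friedman, Mann-Whitney with
    Rosenthal effect sizes, Holm correction). Includes a synthetic gait
    cohort generator with controllable subject, condition, side and trial
    variance components for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    cluster,
    e1071,
    ape,
    nortest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
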