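Package: coaStar
Title: Comprehensive Objective Assessment of Cerebellar Ataxia with STAR
    Decomposition
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for instrumented assessment of
    cerebellar ataxia across five motor domains (speech, upper limb, lower
    limb, balance and gait). Provides a synthetic cohort generator emulating
    wearable inertial, camera-tracking and speech-envelope recordings from
    nine bedside neurological tests; signal-level extraction of 172
    movement features (spectral resonance, multiscale and fuzzy entropy,
    tap-interval variability, dynamic-time-warping tracking error,
    cross-correlation delay, Fitts-law index of performance, syllable
    prosody); per-test principal-component compression to 27 components;
    nonparametric group statistics; Spearman dependency networks with
    minimum-spanning-tree centrality analysis; random-forest binary and
    label-powerset multilabel classification with permutation-importance
    feature-subset selection; and a decomposition of discriminative weight
    into the four Holmesian dimensions of Stability, Timing, Accuracy and
    Rhythmicity (STAR).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    randomForest,
    rpart,
    nnet,
    class,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
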