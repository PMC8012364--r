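Package: csrttpipe
Title: Fiber Photometry, Behavior and Electrophysiology Analysis for the
    5-Choice Serial Reaction Time Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for rodent cognitive-control experiments
    combining fiber photometry, self-paced 5-choice serial reaction time
    task (5-CSRTT) behavior, and whole-cell patch-clamp recordings.
    Implements isosbestic (405 nm) motion correction and delta-F/F
    construction, zero-phase filtering, spectral detrending and
    decimation, trial-aligned baseline z-scoring, delay-period activity
    metrics, bootstrap elevated-window detection and frame-wise
    permutation comparisons with singleton filtering, 5-CSRTT session
    metrics, and intrinsic/synaptic electrophysiology feature
    extraction. A synthetic-data generator with known ground truth
    emulates two-channel photometry recordings, session event logs and
    current-clamp/voltage-clamp sweep sets so that every stage is
    verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    graphics,
    stats,
    utils,
    signal,
    MASS,
    minpack.lm,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
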