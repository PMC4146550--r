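Package: hybridbci
Title: Hybrid Motor-Imagery Brain-Computer Interface Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-branch EEG classification pipeline for two-class motor-imagery
    brain-computer interfaces. One branch extracts oscillatory band-power features
    (event-related desynchronization) with Common Spatial Patterns and classifies
    them with shrinkage-regularized linear discriminant analysis (LDA); the other
    extracts slow movement-related potentials (lateralized readiness potential)
    as channel-wise mean amplitudes with a second shrinkage LDA. The package
    provides supervised per-trial classifier adaptation, a weighted
    meta-combination of the two branch outputs, threshold-gated two-action
    control of a Connect-4 game, closed-loop session simulation (cued copy-task
    and free mode), an evaluation stack (binary accuracy, exact binomial
    chance-level tests, pause-aware Wolpaw information transfer rate,
    leakage-free cross-validation, spectral screening), and a ground-truth
    synthetic EEG generator so that every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
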