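Package: atersp
Title: Active-Touch EEG Time-Frequency Analysis with Single-Trial
    Sensor Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for active-touch electroencephalography
    experiments in which six-axis force/torque recordings of finger
    exploration are fused with EEG at the single-trial level. Provides
    force-plate kinetics (centre of pressure, friction, load, speed),
    velocity-peak movement-onset detection and trial quality control,
    onset-locked epoching, Morlet-wavelet event-related spectral
    perturbation in alpha and beta bands, scalp-time image construction
    with mass-univariate general linear models and cluster-extent
    inference, repeated-measures ANOVAs with Greenhouse-Geisser
    correction, and a synthetic-data generator with known ground truth
    so that every stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    data.table,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
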