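Package: ecogpls
Title: Offline Decoding of 3-D Hand Trajectories from ECoG Band-Power Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline brain-machine-interface analysis pipeline that decodes
    continuous three-dimensional hand position from multichannel
    electrocorticographic (ECoG) surface potentials. Raw recordings are
    common-average referenced, decomposed into physiological frequency bands,
    rectified, Gaussian-smoothed and causally z-score normalized into a
    band-envelope feature tensor; a lag-embedded multi-response partial least
    squares (PLS) decoder is fitted with PRESS-based ten-fold cross-validation
    to choose the number of latent variables. Two electrode-selection
    procedures (location-based groups expanding from the central sulcus and
    performance-based incremental ranking), weight-based frequency-band
    contribution analysis and per-band decoding complete the pipeline. A
    synthetic-data generator with planted coupling structure makes every stage
    testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
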