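Package: vowelconstancy
Title: Spike-Distance Decoding of Vowel Identity During Perceptual Constancy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying how auditory cortical neurons represent vowel
    identity across identity-preserving acoustic transformations (fundamental
    frequency, sound level, location and voicing). Provides parallel-formant
    vowel synthesis, a trial-table and inhomogeneous-Poisson spike-train
    simulator with feature-specific temporal kernels, a single-unit
    spike-distance decoder with leave-one-out cross-validation and exhaustive
    response-window optimization, Gaussian-parameterized permutation tests of
    decoder significance, temporal-multiplexing and task-engagement analyses,
    matched-dataset decoding of sound, choice and accuracy, a
    confidence-weighted population decoder, and behavioral constancy and
    generalization statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
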