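Package: multikin
Title: Kinetics, Competition and Machine-Learning Analysis for Multivalent Peptide Binders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolchain for characterising multivalent
    (dimeric, tetrameric, octameric) peptide binders against a protein target.
    Simulates real-time fluorescence biosensor traces from 1:1 binding kinetics
    and fits them with a globally shared single-exponential model to recover
    association and dissociation rates; implements competitive displacement
    analysis (Hill EC50 fitting with an exact ternary-equilibrium K_i
    correction) and tight-binding direct K_D fits; quantifies peptide
    microarray competition data (background subtraction, duplicate deviation,
    normalisation, neutralisation IC50); and predicts binding parameters from
    amino-acid-composition and linker one-hot encodings with random-forest
    regression under leave-one-out cross-validation, including bootstrap
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    randomForest,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
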