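Package: pxrgap
Title: Gap-Penalized Model Selection and Out-of-Distribution Evaluation for
    PXR Activator Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A QSAR workflow for predicting activators of the pregnane X
    receptor (PXR) from chemical structure, built around a regularization-aware
    model-selection criterion: hyperparameters of random-forest and support
    vector machine classifiers are chosen in cross-validation either by mean
    validation Matthews correlation coefficient or by a gap-penalized score
    that subtracts the mean train-validation gap, favouring models that
    generalize to structurally novel chemistry. Includes molecule
    standardization (largest organic fragment, canonical tautomer via InChI,
    InChI-keyed deduplication) with an auditable filter cascade, dual
    featurization (17 physicochemical descriptors and hashed circular
    fingerprints), similarity-stratified test evaluation, chemical-space
    coverage and Murcko-scaffold diagnostics, consensus virtual screening with
    nearest-neighbor novelty triage, and a synthetic analogue-series benchmark
    generator with scaffold-held-out splits for testing out-of-distribution
    behaviour without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ranger,
    e1071,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
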