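Package: somatodec
Title: Somatotopy Mapping and Offline Neural Decoding for Intracortical
    Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Offline analysis pipeline for multielectrode intracortical
    recordings from motor cortex: conversion of threshold-crossing spike
    counts into smoothed z-scored firing rates, per-channel movement-tuning
    significance and depth of modulation with PCA-located response windows,
    naive Bayes movement-type classification under leave-one-out
    cross-validation, indirect optimal-linear-estimation velocity decoding
    with ridge-regressed per-channel encoding models, a two-state hidden
    Markov model click classifier, and Friedman/Wilcoxon comparisons of
    decoding performance across electrode-array conditions. Includes a
    seeded synthetic cortical-population generator with a configurable
    mediolateral somatotopic gradient so every stage is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
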