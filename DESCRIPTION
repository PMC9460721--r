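Package: ssqeeg
Title: Seizure Prediction from Scalp EEG with Synchrosqueezed Wavelet
    Time-Frequency Images and a Multi-Level-Feature CNN
Version: 0.1.0
Authors@R:
    person("ssqeeg", "developers", email = "ssqeeg@example.org",
           role = c("aut", "cre"))
Description: A patient-specific seizure-prediction toolkit for multichannel
    scalp EEG. Reads EDF recordings and seizure annotations, partitions
    recordings into preictal and interictal periods, computes
    synchrosqueezed continuous-wavelet time-frequency maps per channel,
    converts segments into fixed-size multichannel images, trains a
    multi-level-feature convolutional neural network on those images under
    stratified k-fold cross-validation, and reports segment-based accuracy,
    sensitivity, specificity and false predictions per interictal hour.
    Ships a synthetic-EEG generator with annotated seizures and elevated
    low-frequency preictal rhythms so the full pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
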