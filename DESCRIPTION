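Package: preictal
Title: Patient-Specific Seizure Prediction with a Multi-Frame CNN-LSTM Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end, patient-specific classification of pre-ictal versus
    inter-ictal EEG. One-second multichannel segments are represented two
    ways: as a (2, N, N) tensor stacking a per-segment PCA score plane and
    the channel-wise Pearson correlation plane, and as the raw channel-by-time
    matrix. A multi-frame network extracts instance-based (convolutional) and
    sequence-based (recurrent) features from the two representations in
    parallel, concatenates them, and classifies with a fully connected head.
    Includes single-frame CNN and LSTM baselines and a sequential CNN-LSTM
    baseline, leave-one-seizure-out cross-validation with the usual confusion
    metrics and AUC, a synthetic EEG generator with controllable pre-ictal
    effect size for fully offline testing, EDF ingestion with seizure-merging
    and pre-ictal labelling rules, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    yaml
Config/testthat/edition: 3
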