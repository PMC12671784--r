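Package: cgtnet
Title: Multi-Scale Convolution, GRU and Sparse-Transformer Pipeline for EEG Seizure Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, patient-specific seizure-prediction pipeline for
    multichannel scalp EEG. Provides EDF input/output and seizure annotation
    handling, a seeded synthetic-EEG cohort generator with planted preictal
    theta/alpha signatures, the full preprocessing chain (band-stop and
    high-pass filtering, resampling to 256 Hz, 64 s/32 s sliding-window
    segmentation, short-time Fourier spectrograms, window labelling), factor
    analysis dimensionality reduction with Kaiser retention, the CGTNet
    network (parallel multi-scale 1-D convolution branches, a gated recurrent
    unit layer, sinusoidal positional encoding and a sparse-masked multi-head
    Transformer encoder) implemented with exact hand-derived gradients and an
    Adam optimiser, per-patient stratified k-fold cross-validation, a metric
    and statistical-test suite (accuracy, sensitivity, specificity, F1, MCC,
    AUROC, DeLong and Wilcoxon tests, Cohen's d), and the clinical alarm
    policy (0.5 probability threshold, three-consecutive-window confirmation,
    30-minute refractory period, lead-time validation and false-alarms-per-hour
    reporting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    pROC,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
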