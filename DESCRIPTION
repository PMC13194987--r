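Package: smokesense
Title: Predicting Smoking Lapses and Cravings from Passive Smartphone Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible analysis pipeline for behavioural phenotyping of
    smoking behaviour from passively collected smartphone sensor streams
    (accelerometer, gyroscope, magnetometer, ambient light, time of day).
    Provides a synthetic cohort generator with a configurable pre-event
    movement motif, windowing and class-balancing preprocessing, four deep
    sequence classifiers implemented from first principles (LSTM, 1D-CNN,
    BiLSTM, and a stacked 1D-CNN-BiLSTM), and evaluation harnesses for
    within-subject, phase-transfer and leave-one-participant-out designs with
    confusion-matrix, ROC/AUC, stratified and Friedman-test reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
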