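Package: radSSP
Title: Rank-Based Single-Sample Predictors of Radiotherapy Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and evaluates k-top-scoring-pairs (k-TSP) single-sample
    predictors of ipsilateral breast tumor recurrence on NanoString
    nCounter-style targeted count data. Provides a synthetic cohort generator
    emulating a 248-gene radiosensitivity panel with planted within-sample
    pair-order signal and censored time-to-recurrence outcomes, positive
    control and housekeeping normalization with quality filtering,
    cross-validated k-TSP training stratified by estrogen receptor and
    radiotherapy status, gene-signature scoring (rank-linear, proliferation,
    immune), Kaplan-Meier, log-rank, Cox interaction and ROC evaluation, and
    the consecutive-classifier scheme assigning patients to No-RT, Give-RT
    and More-treatment groups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
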