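Package: lnclocr
Title: Cell-Line-Specific Prediction of lncRNA Subcellular Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a long non-coding RNA accumulates in the
    cytoplasm or the nucleus of a given human cell line, from sequence
    alone. Implements a bank of 1,223 composition- and physicochemical
    correlation-based nucleotide descriptors, labelling of transcripts by
    the sign of the cytoplasmic/nuclear relative concentration index
    (CNRCI, a log2 expression ratio), length filtering and greedy
    redundancy reduction, stratified train/validation splitting, minimum
    redundancy maximum relevance (mRMR) feature ranking, and a
    classical-ML training and evaluation harness with stratified
    five-fold cross-validation and seven confusion-matrix/ranking
    metrics. A synthetic-data generator with planted k-mer composition
    signal makes the whole pipeline testable without any downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils,
    Biostrings,
    ranger,
    xgboost,
    e1071,
    rpart,
    nnet,
    class,
    MASS,
    kernlab
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
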