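Package: promForge
Title: Promoter Classification with Triplet-Embedded Bidirectional LSTMs
    and Motif-Preserving Artificial Negatives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for building and evaluating promoter classifiers on
    fixed-length (300 nt) DNA windows. Constructs motif-preserving
    artificial non-promoter training negatives by block recombination of
    promoter sequences, encodes DNA as overlapping-trinucleotide index
    vectors, trains a bidirectional LSTM classifier (embedding, batch
    normalization, Bi-LSTM, two fully connected layers) with
    validation-loss model selection, and reports threshold metrics
    (balanced accuracy, sensitivity, specificity, precision, F1, MCC)
    together with ROC and precision-recall curve areas. A built-in
    simulator generates promoter-like sequences with planted TATA-box,
    CAAT-box and GC-box motifs so the whole pipeline is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
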