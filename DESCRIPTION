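Package: motifclr
Title: Contrastive Pre-Training of DNA Sequence Encoders for Motif
    Occupancy Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting transcription-factor occupancy of DNA
    motif instances with contrastively pre-trained convolutional sequence
    encoders. Implements a Needleman-Wunsch based sequence similarity
    (match = 1, mismatch = indel = 0, i.e. longest common subsequence),
    length-preserving edit augmentation of fixed-length DNA sequences,
    self-supervised (similarity-thresholded, with neutral pairs) and
    supervised contrastive losses, a small CNN encoder with a DNN
    classifier head, pre-train/fine-tune/baseline training loops, grid
    search, evaluation metrics (precision, recall, F1, ROC-AUC), and a
    planted-motif synthetic data generator so the full pipeline is
    testable without external datasets. User-facing functions take and
    return tibbles and fitted objects support broom-style tidy(),
    glance() and ggplot2 autoplot().
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
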