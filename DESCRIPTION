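Package: gpcoupleR
Title: Predicting GPCR-Transducer Coupling from Protein Language Model Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts G protein-coupled receptor (GPCR) coupling to G protein
    families and beta-arrestins from per-layer protein language model
    embeddings. Implements assay-specific binarization of continuous binding
    activities, PCA feature reduction retaining 95 percent of variance,
    repeated stratified cross-validation with grid search and imbalance
    filtering, attention-head importance by backprojection of classifier
    weights through PCA loadings, differential intramolecular-contact
    log-odds enrichment with segment-level signatures, an embedded GPCRome
    space with NMI-based layer selection, and gain/loss-of-coupling calls
    for missense variants and spliceforms. A deterministic synthetic data
    generator with plantable signal supports end-to-end testing without
    external model inference.
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
    ggplot2,
    generics,
    glmnet,
    e1071,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr
Config/testthat/edition: 3
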