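Package: msgddi
Title: Bipartite Skip-Gram Embeddings of Adverse-Event Reports for
    Drug-Drug Interaction Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns joint embeddings of drug and reaction concepts from
    spontaneous adverse-event reports with a modified skip-gram model whose
    context window is replaced by the bipartite rule "the contexts of a drug
    are all reactions in the same report, and vice versa", trained by
    hierarchical softmax over a Huffman tree. Provides a TF-IDF weighted
    co-occurrence matrix baseline with PCA reduction, stratified
    cross-validated logistic-regression evaluation of drug-pair
    classification by AUROC, cosine-based enrichment of drug-drug
    interaction descriptions validated against System Organ Class labels,
    and a synthetic report generator with planted class structure so the
    whole pipeline is testable without access to regulatory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
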