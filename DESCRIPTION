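Package: coexpanel
Title: Coexpressed Gene Panel Discovery from Metatranscriptomes with Graph
    Infomax Embeddings
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting coexpressed gene panels in
    (meta)transcriptomic expression data. Differentially expressed genes are
    filtered, engineered into a gene graph whose node features combine
    log-normalized FPKM expression with binary subcellular annotations
    (signal peptide, transmembrane domain) and whose edges connect genes that
    are close in a t-SNE layout (distance threshold calibrated to a target
    mean degree). A graph convolutional encoder with tunable self-loop
    strength is trained with the Deep Graph Infomax objective to obtain
    unsupervised node embeddings, which are clustered into gene panels.
    Clusterings are evaluated with the silhouette coefficient and a
    Functional Assignment Score measuring how strongly a pathway's genes
    concentrate in the top-ranked clusters. Downstream utilities provide
    pathway enrichment within panels, hub/signaling panel designation,
    per-panel correlation topology networks with modularity classes and
    landmark genes, and a reactive-oxygen-species production-rate helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
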