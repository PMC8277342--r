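Package: obsclust
Title: Semantic Subtype Discovery from Free-Text Obsession Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for discovering semantic subtypes in short
    free-text reports of obsessive-compulsive symptoms. Raw entries are
    cleaned into phrases, a phrase-level word co-occurrence matrix is built,
    pretrained word vectors are fine-tuned on it by minimising the GloVe
    objective with a Mittens proximity penalty, and the fine-tuned vectors
    are projected to two principal components and clustered with k-means.
    Cluster number is selected by four validity heuristics (silhouette,
    elbow, Calinski-Harabasz, Davies-Bouldin), solution stability is
    quantified by split-half Pearson correlations of inter-word distance
    matrices, and cluster word frequencies are compared with chi-square
    tests. A synthetic-corpus generator with planted semantic themes makes
    every stage testable without access to any proprietary app data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    cluster,
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
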