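Package: meshsim
Title: Ontology-Network Semantic Similarity and Clustering for MeSH-Annotated Document Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes semantic similarity between biomedical documents
    represented as sets of hierarchical ontology headings (Medical Subject
    Headings and their tree numbers). Provides six node- and heading-level
    similarity measures (shortest-path, Wu-Palmer, Leacock-Chodorow, Resnik,
    Lin and Schlicker, the information-content ones backed by a
    structure-based intrinsic IC), average-maximum-match aggregation from
    nodes up to document-document similarity, and a redundancy-free
    map/shuffle/reduce decomposition of the pairwise similarity matrix that
    can be partitioned across workers with an optional pre-shuffle combiner.
    On top of the similarity matrix it offers spectral, agglomerative and
    k-means clustering and normalized mutual information evaluation, plus a
    synthetic planted-topic generator so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
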