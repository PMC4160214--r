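Package: milink
Title: Mutual-Information Link Prediction for Complex Networks
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Link prediction for undirected simple networks (for example
    protein-protein interaction maps) using an information-theoretic score:
    the self-information of a candidate link under a degree-based prior is
    reduced by the mutual information carried by each common neighbour,
    estimated from local clustering. Provides the mutual-information index
    together with six common-neighbour reference indices (CN, RA, LNB-CN,
    LNB-RA, CAR, CRA), train/probe evaluation with exact and sampled AUC and
    precision at L, structural summary statistics including local
    assortativity profiles, reproducible synthetic-graph generators, and a
    command-line interface for edge-list files.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    graphics,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
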