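Package: netpharm
Title: Network Pharmacology Target Aggregation, Hub Consensus, and Module Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for offline network-pharmacology analyses of drug and
    disease target sets: normalization and multi-source aggregation of gene
    symbol lists, Venn-region accounting, expansion of an intersection set
    over a weighted functional-association network, confidence filtering of
    STRING-style protein-protein interaction exports, four-centrality
    (degree, MNC, MCC, EPC) consensus selection of hub genes, MCODE
    molecular-complex detection with seed reporting, hypergeometric
    over-representation analysis with Benjamini-Hochberg adjustment and
    odds-ratio ranking, a permutation normalized-enrichment-score ranking of
    transcription-factor regulons, drug-target-disease tripartite network
    construction and export, and a synthetic planted-structure data
    generator with recorded ground truth for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
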