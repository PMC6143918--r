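Package: modrec
Title: Recursive Module Extraction from Weighted Biological Networks
Version: 0.1.0
Authors@R:
    person("BMDS", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects disease modules (communities of 3 to k nodes) in weighted
    molecular networks by recursively applying Louvain modularity optimization
    seeded with a weighted-PageRank initial partition. Includes the network
    standardization steps used for heterogeneous network collections
    (directed-to-undirected conversion by arc-weight averaging, max-weight
    normalization), a planted-partition / nested-block synthetic benchmark
    generator with normalized-mutual-information scoring, edge-list I/O in the
    tab-separated interchange format, and a command-line interface.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
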