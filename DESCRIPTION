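Package: fnmotif
Title: Functional Network Motifs from Protein and Genetic Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identification of functional network motifs (FNMs): small
    connected graphlets (k = 3-6) exhaustively enumerated in a
    protein-protein interaction network by layered depth-first search over
    integer compositions of the motif size, and retained when genetic
    interactions cover at least half of all node pairs and span from the
    source node to the most distant layer. Includes degree-preserving
    null-model randomization, motif clustering by node overlap,
    complex-merged consensus interaction networks with restricted
    betweenness centrality, transcriptional co-regulation scoring, exact
    enrichment statistics, and a seeded synthetic fixture generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
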