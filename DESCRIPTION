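Package: gfabridge
Title: Hybrid Assembly Graph Resolution with Long-Read Bridging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves bacterial short-read assembly graphs using long reads.
    Provides a bidirected assembly-graph data model with GFA1 input and
    output, selection of the best k-mer graph from a candidate ladder,
    contig multiplicity inference from depth and connectivity, semi-global
    (end-gap-free) long-read alignment, bridge construction from read-pair
    contig paths and long-read alignments with heuristic quality scoring,
    quality-ordered bridge application, circularisation and rotation of
    completed replicons, deterministic synthetic fixtures (genomes, k-mer
    graphs, error-bearing long reads), and truth-based assembly evaluation
    (misassemblies, NGA50, completed replicons).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
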