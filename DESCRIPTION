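Package: graphaln
Title: Bit-Parallel Sequence-to-Graph Matching and Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact matching and unit-cost semi-global alignment of query
    sequences against directed, node-labeled sequence graphs (variation
    graphs, de Bruijn graphs), including cyclic graphs. Implements a
    generalized Shift-And automaton for exact sequence-to-graph matching and
    a generalized Myers bitvector algorithm for semi-global alignment, with
    bit-parallel column merging, a changed-minimum priority rule and a bucket
    priority queue. Ships independent cell-by-cell and Dijkstra edit-graph
    solvers used as correctness oracles, generators for benchmark graph
    topologies (linear, SNP bubble, two-path, de Bruijn tangle), read
    simulation utilities, and GFA / FASTA / FASTQ / GAF-style input and
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
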