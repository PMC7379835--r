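Package: gfalign
Title: Semi-Global Alignment of Long Nucleotide and Protein Sequences to Assembly Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Aligns long, diverged nucleotide sequences and amino-acid
    sequences to assembly graphs in GFA 1.x format (e.g. SPAdes or
    metaSPAdes output).  Alignment proceeds by anchor search on edge
    labels, anchor filtering, heaviest-chain selection, and reconstruction
    of the connecting and terminal paths by shortest-path search over an
    implicit alignment (edit) graph, with a 0-1 BFS fast path for edit
    distance.  Protein queries are aligned through a frame-state variant
    of the alignment graph in which codons are assembled base by base
    along graph paths, stop codons are excluded, and substitution-matrix
    scores are made searchable by a constant-shift transform.  A
    deterministic simulator of genomes, compacted de Bruijn graphs,
    error-prone long reads and mutated proteins supports fully
    self-contained testing and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
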