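Package: kmapr
Title: K-mer Manifold Motif Discovery and Embedding for DNA Sequence Sets
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Motif discovery and visualization for DNA sequence sets (SELEX
    reads, ChIP-seq peak sequences, gene-editing amplicons) built on the
    combinatorics of the k-mer manifold.  Motifs are modelled as Hamming
    balls around a consensus k-mer and detected with a Hamming-ball-ratio
    enrichment test against a Gaussian null fitted on random DNA.  Candidate
    consensuses found at consecutive k-mer lengths are merged, and sampled
    k-mers are projected to two dimensions by a cross-entropy embedding with
    manifold-aware distance smoothing, sigmoid repulsion of distant k-mers
    and a diffusion term that prevents gradient explosion on duplicate
    points.  Includes seeded synthetic-data generators for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    Matrix,
    methods,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
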