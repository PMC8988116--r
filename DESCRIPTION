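Package: phaseasm
Title: De Novo Read Ordering via Phase-Signal Correlation and TSP/QUBO Solvers
Version: 0.1.0
Authors@R:
    person("phaseasm", "developers", email = "phaseasm@example.org",
           role = c("aut", "cre"))
Description: Proof-of-concept overlap-layout pipeline for long, single-end,
    forward-strand DNA reads. Reads are encoded as cumulated-phase signals,
    pairwise overlaps are detected by maximum sliding-window Pearson
    correlation, read ordering is cast as a travelling salesman problem over
    an integer cost matrix with an artificial start vertex, and the resulting
    path is split into contigs using a coverage-informed cost threshold. The
    TSP can be solved with a classical nearest-neighbour + 2-opt heuristic or
    with a QUBO formulation sampled by simulated annealing, including a
    clustering-based decomposition for instances beyond the direct embedding
    limit of current quantum annealers. A synthetic-read generator with
    ground-truth layouts and the matching evaluation metrics make every stage
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
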