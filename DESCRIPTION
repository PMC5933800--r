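Package: motifmix
Title: Partitioning ChIP-Seq Regions into Binding Modes by De Novo
    Mixture-of-Motifs Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions a set of ChIP-reported DNA sequences into disjoint
    binding modes, learning one de novo position weight matrix (with its own
    width) per mode. Assignments of sequences to modes, site positions,
    strands and motif widths are inferred by collapsed Gibbs sampling under
    Dirichlet priors, with an order-2 Markov background model; the number of
    modes is chosen by Bayesian model selection with a prior exponential in
    the number of free parameters. Includes a synthetic-data generator with
    known planted modes and recovery scoring, writers for assignment tables
    and motif matrices, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    parallel,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
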