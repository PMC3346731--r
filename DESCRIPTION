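Package: comimic
Title: Cophylogenetic Codivergence Analysis for Mimetic Radiations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Event-based cophylogenetic reconciliation of a mimic phylogeny
    onto a model phylogeny (codivergence, duplication, model switch, loss)
    under an explicit cost regime, with Monte-Carlo significance tests of
    topological congruence, a node-wise pairwise-distance Spearman test,
    minimise-deep-coalescence (MDC) population-tree inference from gene
    trees, and population-genetic statistics (Watterson's theta, nucleotide
    diversity, between-group divergence). Includes seed-controlled
    generators for codivergent tree pairs, multispecies-coalescent gene
    trees, and JC69 alignments used to validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
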