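Package: vironet
Title: Bipartite Gene-Sharing Network Analysis of Virus Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and dissects bipartite genome-gene family networks for
    double-stranded DNA viruses and related mobile genetic elements. Provides
    pangenome deduplication, compositional gene-content distances, maximum
    likelihood estimation of per-family loss rates under a pure-loss divergence
    model, core-gene classification, Barber bipartite modularity optimized by
    simulated annealing with replicate ensembles and degree-preserving null
    models, iterative supermodule hierarchy construction, connector, hallmark
    and signature gene classification, phage lifestyle enrichment tests, and a
    synthetic-data generator with planted modular structure and ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    ape,
    phangorn,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
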