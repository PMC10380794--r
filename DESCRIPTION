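Package: c1aprofiler
Title: Phylogenomic Profiling of Papain-Family (C1A) Peptidase Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tracing the origin and diversification of the papain
    family (clan CA, family C1A) of cysteine peptidases across the tree of
    life. Provides rooted reference taxonomies with named ancestors (LUCA,
    FECA, LECA), phyletic presence/absence matrices, profile-based
    classification of protein sequences into the eight ancestral eukaryotic
    C1A lineages (cathepsins B, C, X, L, F, H, the 26/29 kDa peptidase and
    the type 1 long C1 peptidase), ancestral gene-content reconstruction by
    Dollo parsimony and a two-state gain/loss Markov model, neighbor-joining
    gene trees with bootstrap support, detection of horizontally transferred
    sequences by conservation-anomaly scoring with independent-event
    clustering, and a fully seeded synthetic-data generator that supplies
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
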