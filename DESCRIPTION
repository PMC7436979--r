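Package: netpharm
Title: Network Pharmacology Screening for Multi-Component Formulas
Version: 0.1.0
Authors@R:
    person("Netpharm", "Developers", email = "netpharm@example.org",
           role = c("aut", "cre"))
Description: A tested, file-driven re-implementation of the network
    pharmacology screening workflow used to study multi-component herbal
    formulas: integration of compound-target and disease-target tables,
    construction of a score-thresholded protein-protein interaction
    subnetwork, extraction of the common-target hub subnetwork with first
    neighbors, median-threshold topological screening of key targets
    (degree, betweenness centrality, closeness centrality),
    hypergeometric/EASE over-representation analysis against GMT gene-set
    collections with disease-pathway mapping, compound-target-pathway
    network assembly, and ligand-normalized docking-score ratio matrices.
    Includes a seeded synthetic-data generator that plants recoverable
    structure (network hubs, an enriched gene set, strong docking pairs) so
    the whole pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    yaml,
    pheatmap,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
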