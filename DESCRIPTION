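Package: netpharm
Title: Network Pharmacology of Multi-Target Compounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for network-level target identification of
    multi-target compounds against a disease drug class. Implements three
    hypergeometric pathway-enrichment statistics over drug targets (distinct
    targets, target node occurrences, and drugs), key-pathway selection and
    the candidate protein universe they define, bipartite drug-target,
    target-pathway and drug-pathway network construction with power-law
    degree diagnostics, extraction of a minimal protein-protein interaction
    sub-network linking putative targets through at most one non-target
    connector, and decomposition of that sub-network into topological
    modules by simulated-annealing modularity maximization. Ships seeded
    synthetic-data generators with planted ground truth (enriched pathways,
    stochastic-block-model modules, planted docking hits) so every stage is
    testable end to end without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
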