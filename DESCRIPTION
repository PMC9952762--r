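Package: OmicsForest
Title: Multi-Omics Network Enrichment via Prize-Collecting Steiner Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates transcriptomic, proteomic and metabolomic
    differential-abundance profiles on a merged gene-metabolite interaction
    network and extracts de novo perturbed subnetworks with a
    prize-collecting Steiner forest (PCSF) solver. Provides gene-level TPM
    aggregation and NSAF spectral-count normalization, Welch-test
    differential abundance with Benjamini-Hochberg control, preranked
    geneset enrichment (running-sum statistic with a permutation null),
    hypergeometric over-representation analysis with Jaccard clustering of
    enriched pathways, a Goemans-Williamson style PCSF heuristic with an
    exact brute-force oracle for small instances, modularity-based
    community decomposition with prize-density ranking of subnetworks, and
    a seeded synthetic-study generator with planted perturbed modules for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
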