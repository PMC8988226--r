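Package: urogenet
Title: Co-Occurrence Network Analysis of Paired Urogenital Microbiome Communities
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for comparing microbial
    communities of paired body sites (vagina and bladder) across cohorts
    from genus-level 16S rRNA count tables. Implements preprocessing
    (genus agglomeration, rarefaction without replacement, per-sample
    abundance filtering, frequency-based contaminant screening), alpha
    and phylogenetic beta diversity with PERMANOVA, community-state
    typing by Ward.D2 clustering of weighted UniFrac distances with
    silhouette-based selection of the number of clusters, SparCC
    compositional correlation estimation with a permutation-derived edge
    threshold, map-equation community detection, betweenness-centrality
    keystone identification, and cross-compartment genus-overlap
    summaries. A synthetic-data module generates compositional count
    tables with planted basis correlations, community state types,
    random phylogenies and DNA-concentration-dependent contaminants so
    every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
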