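Package: miconet
Title: Microbial Community Diversity and Co-Occurrence Network Analysis
    for OTU Count Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of amplicon-derived OTU count tables with
    sample metadata, built around a three-habitat (water, sediment, animal
    intestine) by two-breeding-mode aquaculture design. Provides rarefaction
    to the smallest library, alpha-diversity estimators (Good's coverage,
    Chao1, ACE, Shannon, Simpson dominance) with group tests, Bray-Curtis
    beta diversity with principal coordinates analysis, UPGMA clustering and
    seeded ANOSIM/PERMANOVA permutation tests, taxon composition summaries,
    a bipartite genus-environment association network with a seven-way
    sharing classification, and a thresholded Spearman co-correlation
    network with modularity, betweenness hubs and module recovery against a
    planted ground truth. A log-normal copula community simulator with
    planted correlation modules generates data with the statistical
    structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    igraph,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
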