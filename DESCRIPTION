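Package: haptonet
Title: Diversity, Environmental Drivers, and Co-Occurrence Network
    Robustness for Amplicon ZOTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-denoising analysis of marine protist (pico-haptophyte)
    18S rRNA amplicon count tables: rarefaction and alpha diversity
    (richness, Shannon, Faith's phylogenetic diversity), Bray-Curtis and
    weighted UniFrac dissimilarities with principal coordinates analysis
    and ANOSIM, environmental driver attribution by Mantel tests and LMG
    variance decomposition of distance regressions, Spearman co-occurrence
    network construction with Benjamini-Hochberg control, habitat
    enrichment classification, Louvain modules, topological metrics, and
    network robustness measured as natural connectivity under targeted and
    random node-removal attack. Includes a seeded synthetic-community
    generator that plants habitat contrasts, a temperature driver, and
    correlated ZOTU blocks so every stage can be validated against known
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    geosphere,
    igraph,
    jsonlite,
    picante,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    mclust,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
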