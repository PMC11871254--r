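Package: MicroNetStab
Title: Seasonal Microbial Co-Occurrence Networks and Their Stability
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds signed Spearman co-occurrence networks from bacterial
    and protist OTU tables (|rho| > 0.6, p < 0.05 by default), derives
    single-kingdom and cross-kingdom ("+BP", bacterivorous protozoan
    augmented) network variants, and quantifies network stability with a
    four-index suite: random-removal robustness, efficiency-based
    vulnerability, abundance-weighted cohesion with a taxa-shuffle null
    model, and natural connectivity with its decay slope under node
    removal. Also provides the supporting community statistics (richness,
    Shannon diversity, Bray-Curtis dissimilarity, PCoA, ANOSIM, Mantel and
    partial Mantel permutation tests) and a seeded generator of synthetic
    seasonal bacteria-protist communities with planted correlation blocks
    and trophic couplings, so the full seasonal analysis can be exercised
    end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    vegan,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
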