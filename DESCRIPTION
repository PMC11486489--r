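Package: troponet
Title: Trophic Dependency Networks from Constraint-Based Community Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts hierarchical trophic dependencies in microbial
    communities from genome-scale metabolic models (GSMMs). Provides flux
    balance and flux variability analysis on stoichiometric models, an
    iterative community succession simulator in which secreted compounds
    enrich a shared environment until a trophic fixed point, construction of
    the resulting directed bipartite metabolite-exchange network, untangling
    of the network into plant-microbe (PM) and plant-microbe-microbe (PMM)
    sub-network motifs, and statistical association of motifs with
    sample-level health labels (ANOVA/Tukey, one-sided hypergeometric
    enrichment with Benjamini-Hochberg FDR). Includes deterministic
    generators of toy GSMM communities with planted cross-feeding structure
    so every pipeline stage is testable end to end.
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
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
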