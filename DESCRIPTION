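Package: phyloRisk
Title: Phylogenetic and Spatial Analysis of Plant Extinction Risk
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking IUCN Red List extinction risk to macroevolutionary
    process in species-rich floras. Implements binary and ordinal Red List
    scoring with status-transition G-tests, randomization tests for taxonomic
    selectivity of threat, Blomberg's K with tip-randomization significance,
    disparity-through-time profiles compared against Brownian-motion and
    punctuated (peripatric range-asymmetry) null models, binomial GLMs of
    threat against richness, clade age and net diversification rate with
    partial Mantel tests, and quarter-degree-square spatial analyses (Moran's
    I, Clifford-Richardson-Hemon corrected correlation). A synthetic-data
    generator produces complete datasets with the statistical structure these
    analyses assume, so the full pipeline can be exercised and calibrated
    without access to the original floristic databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    picante
Config/testthat/edition: 3
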