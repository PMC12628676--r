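Package: lakeassembly
Title: Community Assembly Processes from Phylogenetic and Taxonomic Null Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies deterministic versus stochastic assembly of microbial
    communities from pairwise phylogenetic (beta nearest-taxon index, bNTI) and
    taxonomic (Bray-Curtis based Raup-Crick, RCbray) null-model turnover.
    Includes the phylogenetic-signal prerequisite check (environmental optima by
    canonical correspondence analysis and Mantel correlograms with progressive
    Bonferroni correction), partitioning of process contributions across
    spatial, temporal and replicate comparison subsets with exact permutation
    tests, alpha/beta diversity and distance-decay utilities, spatial and
    temporal core-microbiome extraction, and a synthetic-community generator
    that assembles OTU tables under each of the five processes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    geosphere,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    picante,
    biomformat,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
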