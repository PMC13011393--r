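Package: betanull
Title: Null-Model Inference for the Drivers of Microbial Beta-Diversity
Version: 0.1.0
Authors@R:
    person("Intertidal", "Microbiome Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constrained taxonomic null models for community tables (richness-
    and species-pool-conditioned permutation schemes), beta-diversity deviation
    standardized effect sizes, expected beta-gamma relationships under random
    sampling from lognormal species abundance distributions, phylogenetic
    (betaMNTD/betaNTI) and Raup-Crick partitioning of community assembly
    processes, environmental-heterogeneity analysis with distance-based
    redundancy analysis, and a process-labelled synthetic community generator
    for end-to-end validation of the whole inference chain.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
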