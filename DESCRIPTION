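Package: exometab
Title: Defined-Medium Stoichiometry and Microbial Exometabolite Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing defined culture media with controlled
    elemental stoichiometry and for analysing targeted LC-MS exometabolite
    profiles of microbial isolates. Includes a molecular-formula parser and
    carbon/nitrogen accounting for tiered medium formulations, plate-reader
    growth-curve metrics and medium-comparison statistics, peak-table
    blank subtraction, normalisation and depletion/production calling by
    rank-sum test, Bray-Curtis hierarchical clustering of substrate
    utilization profiles, phylogenetic niche-conservatism tests (Mantel
    permutation, within-group profile similarity), and a fully seeded
    synthetic-data generator (Yule trees, Brownian trait evolution,
    replicate peak tables, logistic growth curves) for end-to-end
    validation against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
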