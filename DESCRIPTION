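Package: ripenet
Title: Transcript-Metabolite Integration for Mutant Panels Across Ripening Stages
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for integrating replicate-level metabolite and transcript
    abundance tables from a mutant panel sampled across developmental stages:
    wild-type-matched log2 fold-change tables with Student's t-test stars and
    not-detected propagation, one-way ANOVA with Tukey HSD comparisons,
    stage-specific hierarchical clustering of genotype profiles, pairwise-complete
    Pearson correlation matrices over the joint feature space, and hub-centered
    thresholded correlation networks with node strength. A synthetic-data
    generator simulates mutation-driven flux redistribution on a pathway DAG
    with multiplicative noise, planted correlation modules, and
    limit-of-detection censoring, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    ape
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
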