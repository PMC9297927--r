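Package: csdsim
Title: Complementary Sex Determination Tests and Endosymbiont Thelytoky Models
    for Haplodiploid Wasps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based forward simulation of complementary sex
    determination (CSD) under multi-generation inbreeding pedigrees in
    haplodiploid wasps, with exact enumeration oracles for offspring genotype
    distributions and the expected homozygous fraction of fertilized eggs
    across mother-son and brother-sister cross schemes. Includes closed-form
    sex-ratio expectations under no-CSD, viable and inviable diploid-male
    scenarios, brood-level bookkeeping statistics (all-male brood
    classification and exclusion, sex ratios, emergence proportions,
    zero-diploid-male detection power), a titer-threshold model of
    endosymbiont-induced thelytoky distinguishing one-step from two-step
    (diploidization plus feminization) mechanisms from qPCR relative titers
    and dose-response tables, and synthetic-data generators for every input
    the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
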