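Package: circage
Title: Circular RNA Quantification and Aging-Phenotype Association
Version: 0.1.0
Authors@R:
    person("circage", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for circular RNA (circRNA) aging analyses in
    peripheral blood: back-spliced-junction quantification as reads per
    million (bpm), age-class partitioning of circRNAs from RNase R-enriched
    pools, hypergeometric over-representation of host genes against
    user-supplied gene sets, parental longevity score construction,
    global-mean qPCR normalization, and covariate-adjusted association of
    circRNA expression with cohort phenotypes, cellular senescence and
    mouse median strain lifespan. Includes a seeded synthetic-data
    generator with planted ground truth so every downstream stage is
    testable by recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
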