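Package: wolfpva
Title: Individual-Based Population Viability Analysis for a Reintroduced Wolf Population
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pedigree-aware individual-based demographic-genetic simulation for
    population viability analysis (PVA) of a reintroduced social carnivore
    descended from a small captive founder group. Provides pedigree kinship and
    gene-dropping genetics (gene diversity, founder genome equivalents,
    effective size from heterozygosity decline), an annual-cycle wild-population
    simulator with breeder monopolization, inbreeding depression masked by
    supplemental feeding, disease catastrophes, population-cap removals and
    releases from a genetically managed captive population, a factorial
    sensitivity analysis partitioning the contrast between two PVA
    parameterizations into biological, policy and mixed sources via
    standardized regression coefficients, and response surfaces of extinction
    risk and genetic-diversity retention over management levers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
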