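Package: strpop
Title: Population Structure, Diversity and Forensic Statistics for STR Panels
Version: 0.1.0
Authors@R:
    person("strpop", "maintainers", email = "strpop@example.org",
           role = c("aut", "cre"))
Description: Analysis of multi-allelic short tandem repeat (STR) genotype
    panels for population-structure studies: gene-counting allele frequency
    estimation with Hardy-Weinberg exact testing, gene diversity and forensic
    parameters (matching probability, power of exclusion, Nei's Gst), Nei's
    D_A genetic distance with neighbor-joining trees and locus-bootstrap
    support, principal component analysis of the locus-averaged covariance
    matrix of allele frequencies, the Harpending-Ward R-matrix gene-flow
    regression, great-circle and ordinal linguistic distance matrices, and
    Mantel / partial Mantel permutation tests. Includes a Balding-Nichols
    style simulator of drifted and isolation-by-distance structured STR
    panels so every stage is testable without external data, plus an
    end-to-end pipeline driver and command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
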