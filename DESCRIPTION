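Package: rapidgs
Title: Rapid-Cycling Genomic Selection: Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulation and analysis toolkit for rapid-cycling
    recurrent genomic selection in landrace-derived populations. Simulates
    a panmictic heterozygous founder population with correlated polygenic
    traits, doubled-haploid (DH) line extraction, and multi-environment
    plot-level phenotypes; implements GBLUP with REML variance components
    (single- and multi-trait), VanRaden method-1 genomic relationships,
    modified Rogers' distances with principal coordinate analysis, a
    multi-trait selection criterion combining directional and stabilizing
    selection, contribution-capped truncation selection with
    distance-maximizing mate allocation, and the downstream analysis layer:
    adjusted entry means and heterogeneous variance components from
    incomplete-block multi-environment trials, entry-mean heritability,
    selection-response regressions, prediction accuracies with retraining,
    and bootstrap comparisons of prediction abilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
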