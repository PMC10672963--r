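Package: fluxpath
Title: Condition-Specific Flux-Weighted Metabolic Pathway Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes condition-specific production and consumption pathways
    for every metabolite in a genome-scale metabolic model and scores
    differential gene expression onto them. A steady-state flux distribution
    is estimated by flux balance analysis with a small quadratic flux-length
    penalty; for each metabolite the active subnetwork within a chosen
    reaction distance is extracted, closed to mass balance, and decomposed
    into elementary flux modes whose weighted sum reproduces the subnetwork
    flux. Modes through the metabolite are summed into a normalized,
    flux-weighted pathway. Expression fold changes are averaged per reaction
    over its catalyzing genes and combined into flux-weighted pathway
    perturbation scores with permutation p-values, subsystem hit scores, and
    a multi-condition pathway database merged by Matthews correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
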