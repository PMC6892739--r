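Package: pediar
Title: Phenotype-Driven Gene Prioritization from Exome and Facial-Gestalt Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates per-gene variant deleteriousness scores with
    gene-mapped phenotype evidence (facial-gestalt similarity vectors and
    three HPO-based semantic similarity scores: a symmetric Resnik
    best-match-average, a Bayesian ontology query posterior, and a
    closure-overlap feature match) into a single prioritization score per
    candidate gene using a linear support vector machine. Includes a
    spike-in exome benchmark simulator, gene-disjoint cross-validation,
    top-k accuracy and rank-sensitivity evaluation, score-combination
    ablations, and a score-borrowing transfer experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    e1071,
    vcfR,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
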