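Package: methdriver
Title: Methylation-Informed Prediction of Cancer Driver Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts cancer driver genes by integrating two evidence
    streams from paired tumor/normal cohorts. A primary expression layer
    identifies putative oncogenes and tumor suppressors (oncogenic
    mediators) from differential expression, a mutual-information gene
    regulatory network, and signed effect scores on cancer-growing and
    cancer-blocking processes. A secondary methylation layer models
    per-CpG beta values with beta mixtures, calls hypo-, hyper- and
    dual-methylated states against normal tissue, and tests the
    association of each methylation state with gene expression. The two
    layers are reconciled through an explicit agreement/conflict rule
    table: mediators whose methylation state supports their putative role
    are emitted as driver genes. Includes census-based evaluation
    (precision, sensitivity, Fisher's exact test), a synthetic-cohort
    generator with planted methylation-driven drivers, and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
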