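Package: treghub
Title: Treg Hub-Gene Discovery and Immune-Checkpoint Combination Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for identifying regulatory T cell (Treg)
    hub genes from bulk RNA-seq count data and scoring cancer indications
    for combination therapy with immune checkpoint inhibitors. Implements
    negative-binomial Wald differential expression (median-of-ratios size
    factors, method-of-moments dispersions, IRLS GLM fits), cross-dataset
    DEG intersection with direction consistency, hypergeometric
    over-representation analysis against GMT gene-set collections,
    protein-protein interaction centrality analysis and hub ranking from
    STRING-format edge lists, pan-cancer Spearman correlation of a target
    gene with checkpoint genes and with tumor mutational burden (TMB) and
    microsatellite instability (MSI), and a rubric-based integrated
    indication score. A synthetic-data module generates every input the
    pipeline consumes, with planted ground truth, so all stages are
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
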