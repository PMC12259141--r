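Package: boolimpl
Title: Boolean Implication Networks and Composite Gene Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers Boolean implication networks from gene-expression
    matrices. Each gene is discretized into low/intermediate/high calls by
    fitting a single rising step to its sorted expression values (the
    StepMiner threshold with a +/-0.5 log2 noise margin), gene pairs are
    classified into one of six Boolean implication relationships via
    sparse-quadrant statistics, equivalence edges are clustered with
    Jaccard pruning into a clustered implication network, and up/down gene
    signatures are trained from cluster candidates with ROC-AUC filters and
    t-statistic ranking, then evaluated as modified Z-score composite
    scores. A synthetic-data generator with planted Boolean structure makes
    the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
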