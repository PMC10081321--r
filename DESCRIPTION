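Package: coexfid
Title: Co-Expression Fidelity Scoring for Single-Cell RNA-Seq Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds rank-standardized aggregate gene co-expression networks
    from single-cell RNA-seq datasets, derives meta-analytic cell-type
    markers by recurrent differential expression, and quantifies how well a
    query dataset preserves reference co-expression at gene, gene-set and
    genome-wide resolution. Includes neighbor-voting (guilt-by-association)
    module scoring, a mean-sample-error z-test for gene-set preservation,
    permutation tests for correlation significance, hypergeometric gene-set
    enrichment, consensus k-means evaluation of marker modularity, and a
    synthetic-data generator with planted cell-type marker programs and
    tunable co-expression preservation for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    data.table,
    stats,
    utils,
    jsonlite,
    yaml,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
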