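Package: anhydronet
Title: Gene Regulatory Network Analysis for Desiccation-Tolerance Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Infers and dissects transcriptional regulatory networks from
    time-series expression experiments of the kind used to study anhydrobiosis
    (trehalose pretreatment followed by rehydration). Provides negative-binomial
    likelihood-ratio tests for time-course differential expression, boosted-tree
    regulatory scoring with scale-free threshold selection and lag-1
    cross-correlation edge signs, a signed three-node motif census
    (feed-forward and feedback loops) with an Erdos-Renyi randomization null,
    topological-overlap coexpression module detection with pseudo-F cluster-size
    selection, joint motif-enrichment and Granger-causality regulation calls,
    cross-species network comparison and contraction to a desiccation-specific
    core, and a synthetic-data generator with planted network, module, and
    promoter-motif structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    igraph,
    xgboost,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    lmtest,
    withr
Config/testthat/edition: 3
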