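Package: qsconsensus
Title: Consensus Evaluation of Protein Quaternary Structure Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates protein quaternary structure (stoichiometry and point
    group symmetry) annotations by combining four independent predictors:
    sequence-identity clustering with a within-cluster consistency score,
    literature text mining (tf-idf, feature hashing, sentence classification),
    and adapters for PISA-style and EPPIC-style assembly predictions. A
    majority-vote consensus aggregates the per-method calls, and a benchmark
    evaluator classifies predictions as correct, incorrect, inconclusive, or
    not available. Includes an operator-based point-group classifier with
    group-closure validation and deterministic synthetic-fixture generators
    (annotated sequence clusters, labelled sentence corpora, assembly XML,
    benchmark tables with planted ground truth) so the full pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    xml2,
    igraph,
    kernlab,
    caTools,
    pROC,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
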