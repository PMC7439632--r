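Package: trajpath
Title: Disease Trajectory Classification from Predicate Paths in Protein
    Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decides whether an ordered pair of diseases forms a disease
    trajectory (a temporal sequence of diagnoses) from the predicate-labelled
    paths that connect the two diseases' protein sets in a biomedical
    knowledge graph.  Enumerates overlap, direct, and indirect (two-triple)
    protein paths, encodes them as binary metapath or split-path features with
    or without predicate directionality, and evaluates random-forest
    classifiers under repeated, fold-matched cross-validation with paired
    significance testing, undersampling, and ROC/Youden reporting.  Includes a
    synthetic benchmark generator that plants a tunable association between
    trajectory direction and predicate orientation so the whole pipeline is
    testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Matrix,
    ranger,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
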