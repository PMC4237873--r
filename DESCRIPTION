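Package: clintemprel
Title: Temporal Relation Identification and Classification for Clinical Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A knowledge-rich hybrid system for identifying and classifying
    temporal relations (TLINKs) between clinical events and time expressions
    in discharge summaries annotated in the i2b2 dialect. Implements the
    12-type fine-grained relation taxonomy with inversion and the mapping to
    the three broad shared-task types, feature extraction over gold linguistic
    annotation layers (lexical, grammatical, entity-attribute, distance,
    semantic-role, discourse and medical semantic-relation features), an
    11-class medical semantic-relation ensemble (flat-feature SVM,
    convolution tree-kernel SVM bank and a weighted nearest-neighbour
    classifier combined by fixed probability weights), an accuracy-ordered
    hand-crafted rule engine, four specialized relation classifiers, a
    relation identification stage with tunable decision thresholds, micro and
    macro scoring plus closure-based TLINK scoring, and a seeded synthetic
    corpus generator so that every component is testable without the
    access-restricted challenge corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    xml2,
    jsonlite,
    yaml,
    e1071,
    kernlab,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
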