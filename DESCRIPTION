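Package: exprquery
Title: A Query Language for Filtering, Sorting and Cross-Associating
    Expression Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A small domain-specific query language (FILTER / SORTER /
    MAXROWS) evaluated natively over pre-joined gene- or
    transcript-expression tables.  Supports boolean and arithmetic
    expressions over numeric sample columns, substring predicates over
    description and Gene Ontology annotation columns, cross-dataset
    association on shared identifiers, CSV and JSON export, saved
    queries, and deterministic synthetic-fixture generation for testing
    query pipelines without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
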