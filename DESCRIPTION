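Package: cidre
Title: Chemical-Induced Disease Relation Extraction from Biomedical Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid system for detecting chemical-induced disease (CID)
    relations in Medline-style abstracts annotated in the BC5-CDR PubTator
    interchange format. Combines three complementary detectors: high-precision
    sentence-level trigger patterns ("CHEMICAL-induced DISEASE" and related
    families), a shallow-linguistic support vector machine relation classifier
    with entity-blinded n-gram context features, and a knowledge base of known
    therapeutic-indication and side-effect associations used both to select
    known side effects and to filter out drug treatments. Includes the
    crowdsourced-corpus aggregation procedure (majority voting over redundant
    worker judgments, corpus balancing), document-level precision/recall/F
    evaluation, and a seeded synthetic-corpus generator so every stage is
    testable without external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
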