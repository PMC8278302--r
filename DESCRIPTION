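Package: pmrank
Title: Two-Phase Precision-Medicine Literature Retrieval and Re-Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for retrieving treatment-focused
    biomedical abstracts for precision-medicine topics (disease, genetic
    variant, demographic). Initial retrieval uses a fielded Okapi BM25 index
    with knowledge-base query expansion (disease synonyms, treatment
    keywords) and per-field query boosting. Retrieved documents are
    re-ranked by an ensemble of a bidirectional-GRU attention classifier
    (treatment focus) and a MatchPyramid relevance matcher (disease match),
    fused by three one-vs-rest logistic regressions or a voting rule into a
    three-level relevance label that drives a tiered re-ranking. Includes
    TREC run/qrels I/O, graded-relevance metrics (P@10, R-precision, NDCG)
    and a seeded synthetic-corpus generator so every stage is testable
    without external collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
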