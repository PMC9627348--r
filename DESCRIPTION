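Package: kgsearch
Title: Knowledge-Graph-Embedding Semantic Search over Biomedical Literature Metadata
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds a typed knowledge graph from relational article-metadata
    tables (articles, authors, extracted bio-entity mentions, citations,
    funding projects, MeSH assignments), embeds its nodes with p/q-biased
    second-order random walks and skip-gram with negative sampling, pools node
    vectors into article and query vectors, and ranks articles by cosine
    similarity. Includes a synthetic metadata generator with planted topical
    structure, a free-text query frontend (tokenization, sliding-window
    expansion, Levenshtein entity matching), a TF-IDF ranking baseline, and a
    ranked-retrieval evaluation harness (precision/recall/F1 at K, MAP).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
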