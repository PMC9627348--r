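---
title: "Semantic literature retrieval with knowledge-graph embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic literature retrieval with knowledge-graph embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgsearch)
```

## The retrieval model

Literature search engines that rank by lexical overlap (TF-IDF and its
descendants) cannot tell that an article about *insulin resistance* is
relevant to a query about *type 2 diabetes* unless the strings co-occur.
`kgsearch` implements the alternative this package is built around: encode
the *metadata* of a bibliographic corpus — authorship, extracted bio-entity
mentions (drugs, diseases, genes, species), citations, funding projects and
MeSH assignments — as a typed knowledge graph, embed every node of that
graph in a common Euclidean space, and rank articles by the cosine between a
query vector and pooled article vectors. Relevance then flows through the
graph: two articles that cite each other, share authors, or mention the same
disease end up close in the embedding space even when their token sets are
disjoint.

The pipeline has five stages.

1. **Graph construction.** Each metadata row becomes one triple, e.g.
   `("article/pmid/86509", "article-writtenBy-author", "author/aid/6754")`.
   Node identity is the original identifier prefixed by its type, so the
   graph is a typed, undirected multigraph over nine node types (articles,
   authors, four bio-entity types, NIH projects, MeSH terms, chemical
   substances) and nine edge labels. Duplicate triples, and both
   orientations of a bidirectional relation, collapse to a single labeled
   edge: nothing downstream uses multiplicity.

2. **Node embedding.** A second-order biased random walk samples a corpus of
   node sequences. Having stepped from `prev` to `cur`, the unnormalized
   probability of moving to a neighbor `x` of `cur` is `1/p` when
   `x == prev`, `1` when `x` is also a neighbor of `prev`, and `1/q`
   otherwise. Skip-gram with negative sampling then maximizes, for every
   in-window pair of walk positions, `log σ(u_o·v_c) + Σ_j log σ(−u_j·v_c)`
   with the `j` drawn from the unigram distribution raised to 0.75. The
   released vectors are the input (center) vectors. Edge labels are ignored
   during walking: the embedding captures structure, not relation semantics,
   which is a known limitation of this model family.

3. **Article pooling.** Stage 1 averages, for every article node, the raw
   vectors of *all* first-order neighbors regardless of type. Stage 2
   averages, for each searchable article, the stage-1 vectors of its
   first-order *article* (citation) neighbors. The two stages use each
   neighborhood reading once — all-type pooling and article-only pooling —
   which is the only combination consistent with both descriptions of the
   procedure we follow; both type filters are arguments to
   `pool_neighbors()` if a different reading is wanted. An article's own
   vector is not included at either stage; an article without citation
   neighbors falls back to its stage-1 vector, and an isolated article to
   its raw node vector.

4. **Query understanding.** Queries are lower-cased, stripped of punctuation
   and stop words, and split on whitespace; the token list is expanded with
   sliding windows of sizes 2, 3 and 4 (originals first, then n-grams by
   ascending size, left to right). Every keyword is matched against the
   bio-entity index by Levenshtein distance; the minimum-distance mention at
   distance ≤ 1 wins, ties going to the lexicographically smallest mention.
   The query vector is the mean of the matched entities' *raw node* vectors
   (not their pooled article vectors: the matcher returns entity nodes). A
   query in which no keyword matches is a clean "no results" outcome, not an
   error.

5. **Ranking and evaluation.** Articles are sorted by cosine score,
   descending, ties broken by ascending PMID for determinism, truncated to
   K. The evaluation harness computes precision, recall, F1 and MAP at each
   K of a 12-level grid (1–1000), averaged over queries, for the embedding
   ranker and a TF-IDF baseline fitted on title+abstract tokens.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `dim` | 128 | embedding dimension |
| `window` | 5 | skip-gram context radius (walk positions) |
| `negatives` | 7 | noise samples per positive pair |
| `p` | 2 | return bias; weight 1/p to revisit the previous node |
| `q` | 0.5 | in-out bias; q < 1 explores depth-first |
| `walk_length` | 50 | nodes per walk |
| `walks_per_node` | 5 | walks started at every node |
| `epochs` | 5 | training passes over the walk corpus |
| `alpha` | 0.025 | initial learning rate, linear decay to `alpha_min` |
| `noise_exponent` | 0.75 | unigram noise distribution exponent |
| `max_distance` | 1 | Levenshtein threshold for entity matching |
| `windows` | 2,3,4 | query-expansion n-gram sizes |

`dim`, `window`, `negatives`, `p`, `q`, `walk_length` and `walks_per_node`
are the operating point the method was designed around. The training
schedule (epochs, learning rate, noise exponent) is not pinned down by the
method's description; we use the standard skip-gram conventions — linear
learning-rate decay from 0.025 and a 0.75-power unigram noise distribution —
and 5 epochs, which is enough for the walk corpus to be seen repeatedly at
the corpus sizes we target. Every node is kept in the vocabulary
(`min_count = 1` in word2vec terms) because each knowledge-graph node must
receive a vector.

Two readings in the source material were genuinely open and are worth
recording. First, the labels of `p` and `q` appear once with their roles
swapped relative to the standard second-order-walk definition; we keep the
standard definition (p = return, q = in-out) and read the swapped sentence
as describing the chosen values. Second, the query-expansion example shows
windows {2, 3} while the prose says {2, 3, 4}; `expand_query()` exposes the
window set, defaulting to {2, 3, 4}, and reproduces the printed example with
{2, 3}. Precision and recall are implemented in their universal definitions
(the description we follow swaps the two words in prose while its reported
behavior matches the standard forms). Both average-precision variants are
shipped — `"standard"` (mean precision at relevant ranks, normalized by
`min(|relevant|, K)`) and `"all-positions"` (mean precision at every rank
≤ K) — because the prose describes the latter while the former is the
field's convention; the default is `"standard"`.

The optional verb filter in `tokenize_query()` uses a small built-in
lexicon of imperative search verbs rather than a part-of-speech tagger, and
is off by default; the default stop-word list already covers the common
query scaffolding ("show me … on …").

## What the synthetic corpus emulates — and what it does not

`generate_tables()` produces the relational tables a PubMed-style KG is
built from, with planted structure so retrieval quality is measurable
against known truth:

* articles are assigned to `n_topics` topics in balanced fashion;
* each of the four bio-entity types has `entities_per_topic` entities per
  topic; an article's mentions are drawn from its own topic's pool with
  probability 0.85, otherwise from another topic;
* every entity has `mention_variant_count` surface strings: the base name,
  a case variant, and suffixed variants at edit distance 1, so fuzzy
  matching is exercised;
* citations point to earlier-indexed articles and stay within the citing
  article's topic with probability `citation_intra_topic_prob` exactly: the
  intra/inter side is drawn first and the citation is skipped when that
  side has no remaining candidate, so the realized intra-topic fraction is
  binomial around the configured rate;
* abstract token streams contain the article's mention strings plus filler
  tokens from a vocabulary disjoint from all entity names, which makes the
  TF-IDF baseline's behavior analyzable (it can only score on mention
  tokens);
* ground truth is exact: an article is relevant to an entity iff it
  mentions it, and evaluation queries are surface mentions of sampled
  entities.

The default configuration — 200 articles, 4 topics, 3 entities per type per
topic, 2–6 citations per article at 0.9 intra-topic probability — is the
reference corpus used by the package's tests and by
`scripts/acceptance.R`. It is deliberately small enough that the full
pipeline runs in under a minute.

Because the filler vocabulary is disjoint from entity names and abstracts
literally contain the queried mention strings, the TF-IDF baseline is
*strong* on this corpus — often near-perfect at small K — unlike on real
literature where lexical gaps are the norm. Passing tests on synthetic data
therefore demonstrate that the machinery recovers planted structure
(relevant articles score higher cosine than non-relevant ones; precision@5
beats the random-ranker expectation), not that the embedding ranker beats
TF-IDF under lexical mismatch; the synthetic corpus has no mismatch to
exploit. Other aspects of real metadata the generator does not model:
citation-age distributions, author-name ambiguity, skewed topic sizes, and
the long-tailed degree distributions of real citation networks.

## Numerical choices and degenerate inputs

* **Determinism.** Walk sampling and skip-gram training run single-threaded
  on a self-contained xorshift128+ generator seeded from the configuration,
  so a seed reproduces walks, embeddings, rankings and written reports
  byte-for-byte. R-level sampling (table generation, query planting) goes
  through R's RNG under locally-scoped seeds derived from the master seed.
* **Ties.** Rankings break score ties by ascending PMID; entity matching
  breaks distance ties by the lexicographically smallest mention string,
  then the smallest entity id.
* **Dead ends.** Walks truncate at isolated nodes (the only dead ends in an
  undirected graph); a single-node corpus still yields a d-dimensional
  vector (its initialization) rather than an error.
* **Zero vectors.** Cosine of a zero vector is an error at the primitive
  level; the ranker instead scores articles with zero stage-2 vectors at
  −Inf so they sort last rather than aborting a whole query.
* **Empty outcomes.** An all-stop-word query tokenizes to an empty list and
  surfaces as "no results"; a fully out-of-vocabulary TF-IDF query returns
  an empty ranking; a ranker failure inside the benchmark scores that query
  0 and the run continues.
* **Sigmoid clipping.** Training clips logits to ±8 before the sigmoid, the
  usual word2vec guard against overflow; the R-level
  `negative_sampling_loss()` is exact and is what the gradient tests check
  against finite differences.

## Problem sizes

The test suite and the acceptance script run the full pipeline on the
200-article reference corpus (about 400 nodes and 2,000 edges; roughly 100k
walk tokens per run) and repeat the end-to-end signal-recovery check over
three seeds; mechanical checks (transition law, gradients, metric oracles)
use toy graphs of up to 50 nodes and 1,000 random metric instances. These
sizes were chosen so the whole suite exercises every stage, seeds included,
in a few minutes on one CPU.

## Known limitations

* The embedding is structure-only: edge labels and node types do not enter
  the objective, so relation semantics are not distinguishable in the
  space.
* Entity matching is string-level (Levenshtein ≤ 1 by default); it will not
  bridge synonyms that share no surface form — that is the job of the
  upstream entity normalization that produced the mention tables.
* Query vectors average all matched entities; multi-intent queries are
  blended rather than disambiguated.
* MAP at large K decays for any ranker that retrieves the whole corpus,
  because the positions of irrelevant documents dilute the average; compare
  rankers at matched K.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  synth = synth_config(n_articles = 200, n_topics = 4),
  n_queries = 15, seed = 1
)
res <- run_pipeline(cfg)
report_table(res$report)

# interactive search against the built state
state <- res[c("graph", "index", "emb", "art_vecs")]
kg_search(res$queries$text[1], state, k = 5)
```
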