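# A small KG: three articles in a citation chain, one author, one drug.
#   article/1 -- author/7, article/1 -- drug/5, article/2 cites article/1,
#   article/3 is uncited and cites nothing; article/3 -- drug/5
pool_fixture <- function() {
  types <- c("article/pmid/1" = "article", "article/pmid/2" = "article",
             "article/pmid/3" = "article", "author/aid/7" = "author",
             "bioentity/drug/5" = "drug")
  edges <- data.frame(
    from = c("article/pmid/1", "article/pmid/1", "article/pmid/2", "article/pmid/3"),
    to = c("author/aid/7", "bioentity/drug/5", "article/pmid/1", "bioentity/drug/5"),
    label = c("article-writtenBy-author", "article-mentions-drug",
              "article-cites-article", "article-mentions-drug"))
  g <- toy_graph(edges, types)
  emb <- rbind(
    "article/pmid/1" = c(1, 0),
    "article/pmid/2" = c(0, 1),
    "article/pmid/3" = c(1, 1),
    "author/aid/7"   = c(3, 3),
    "bioentity/drug/5" = c(1, -1))
  list(g = g, emb = emb)
}

test_that("neighbor pooling is the arithmetic mean of selected vectors", {
  fx <- pool_fixture()
  # all-type neighbors of article 1: author (3,3), drug (1,-1), article 2 (0,1)
  expect_equal(pool_neighbors(fx$g, fx$emb, "article/pmid/1"),
               c(4 / 3, 1))
  # article-only pooling
  expect_equal(pool_neighbors(fx$g, fx$emb, "article/pmid/1",
                              neighbor_types = "article"),
               c(0, 1))
  # single neighbor returns that vector exactly
  expect_equal(pool_neighbors(fx$g, fx$emb, "author/aid/7"), c(1, 0))
  # include_self folds in the node's own vector
  expect_equal(pool_neighbors(fx$g, fx$emb, "author/aid/7", include_self = TRUE),
               c(2, 1.5))
  # no qualifying neighbor -> undefined-vector error
  expect_error(pool_neighbors(fx$g, fx$emb, "author/aid/7",
                              neighbor_types = "drug"),
               class = "kgsearch_undefined_vector")
  # permutation invariance: pooling identical vectors returns that vector
  same <- rbind("article/pmid/1" = c(2, 2), "author/aid/7" = c(5, 5),
                "bioentity/drug/5" = c(5, 5), "article/pmid/2" = c(5, 5))
  expect_equal(pool_neighbors(fx$g, same, "article/pmid/1"), c(5, 5))
})

test_that("article vectors follow the two-stage pooling with fallbacks", {
  fx <- pool_fixture()
  av <- article_embeddings(fx$g, fx$emb)
  s1_a1 <- colMeans(fx$emb[c("author/aid/7", "bioentity/drug/5", "article/pmid/2"), ])
  s1_a2 <- fx$emb["article/pmid/1", ]            # single neighbor
  s1_a3 <- fx$emb["bioentity/drug/5", ]          # single neighbor
  expect_equal(av$stage1["article/pmid/1", ], s1_a1)
  expect_equal(av$stage1["article/pmid/2", ], s1_a2)
  # stage 2: article 2 has one citation neighbor (article 1) -> its stage-1
  expect_equal(av$stage2["article/pmid/2", ], s1_a1)
  # article 3 has no citation neighbors -> its own stage-1 vector
  expect_equal(av$stage2["article/pmid/3", ], s1_a3)
  expect_error(article_embeddings(fx$g, fx$emb, targets = c(1, 99)),
               class = "kgsearch_missing_target")
})

test_that("query vectors average matched entity vectors", {
  fx <- pool_fixture()
  ms <- structure(list(matched = data.frame(keyword = "x", mention = "x",
                                            entity_id = 5, entity_type = "drug",
                                            distance = 0L),
                       unmatched = character(0)), class = "match_set")
  expect_equal(embed_query(ms, fx$emb), c(1, -1))
  emb2 <- rbind(fx$emb, "bioentity/disease/6" = c(0, 2))
  ms2 <- ms; ms2$matched <- rbind(ms$matched,
    data.frame(keyword = "y", mention = "y", entity_id = 6,
               entity_type = "disease", distance = 0L))
  expect_equal(embed_query(ms2, emb2), c(0.5, 0.5))
  empty <- structure(list(matched = ms$matched[0, ], unmatched = "q"),
                     class = "match_set")
  expect_error(embed_query(empty, fx$emb), class = "kgsearch_no_match")
  ms3 <- ms; ms3$matched$entity_id <- 999
  expect_error(embed_query(ms3, fx$emb), class = "kgsearch_missing_node")
})

test_that("cosine similarity obeys its identities", {
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(c(2, 2), c(1, 1)), 1)
  expect_equal(cosine_sim(c(1, 2, 3), c(4, 5, 6)), 0.974632, tolerance = 1e-5)
  expect_error(cosine_sim(c(0, 0), c(1, 1)), class = "kgsearch_zero_vector")
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(5); s <- runif(1, 0.1, 9)
    expect_equal(cosine_sim(a, b), sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
    expect_equal(cosine_sim(a, b), cosine_sim(b, a))
    expect_equal(cosine_sim(s * a, b), cosine_sim(a, b))
    expect_lte(abs(cosine_sim(a, b)), 1 + 1e-12)
  }
})

test_that("ranking sorts by score with pmid tie-breaks and prefix-consistent truncation", {
  av <- structure(list(stage2 = rbind(
    "article/pmid/3" = c(1, 0),
    "article/pmid/1" = c(1, 1),
    "article/pmid/2" = c(1, 1),
    "article/pmid/4" = c(0, 1)), targets = 1:4, dim = 2),
    class = "article_vectors")
  r <- rank_articles(c(1, 1), av, k = 10)
  expect_equal(r$pmid, c(1, 2, 3, 4))          # tie between 1 and 2 -> lower pmid
  expect_equal(r$score[1], 1)
  expect_equal(r$rank, 1:4)
  expect_true(all(diff(r$score) <= 1e-12))     # non-increasing
  # top-K is a prefix of top-K'
  expect_equal(rank_articles(c(1, 1), av, k = 2)$pmid, r$pmid[1:2])
  # query equal to one vector, others orthogonal
  av2 <- structure(list(stage2 = rbind("article/pmid/8" = c(0, 2),
                                       "article/pmid/9" = c(3, 0)),
                        targets = 8:9, dim = 2), class = "article_vectors")
  r2 <- rank_articles(c(0, 1), av2, k = 1)
  expect_equal(r2$pmid, 8)
  expect_equal(r2$score, 1)
})

test_that("end-to-end search returns deterministic rankings or a clean no-match", {
  tb <- generate_tables(synth_config(n_articles = 60, n_topics = 3, seed = 2))
  g <- assemble_graph(build_triples(tb))
  cfg <- embedding_config(dim = 32, epochs = 3, seed = 3)
  emb <- train_skipgram(sample_walks(g, cfg), cfg)
  state <- list(graph = g, index = build_entity_index(tb$mentions), emb = emb,
                art_vecs = article_embeddings(g, emb))

  miss <- kg_search("qqqq xxxx", state)
  expect_s3_class(miss, "search_no_match")
  expect_identical(miss$status, "no_match")

  q <- tb$mentions$mention[1]
  r1 <- kg_search(q, state, k = 20)
  r2 <- kg_search(q, state, k = 20)
  expect_identical(r1$pmid, r2$pmid)
  expect_true(all(is.finite(r1$score)))
  # every article mentioning the planted entity is scored
  eid <- tb$mentions$entity_id[1]
  rel <- tb$truth$pmid[tb$truth$entity_id == eid]
  full <- kg_search(q, state, k = Inf)
  expect_true(all(rel %in% full$pmid))
  expect_type(attr(r1, "log"), "list")
})
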