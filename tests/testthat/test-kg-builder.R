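test_that("node ids are canonical typed prefixes", {
  expect_identical(make_node_id("article", 652148), "article/pmid/652148")
  expect_identical(make_node_id("author", 6754), "author/aid/6754")
  expect_identical(make_node_id("nih_project", 4123), "nih_project/project_id/4123")
  expect_identical(make_node_id("drug", 1256), "bioentity/drug/1256")
  expect_error(make_node_id("journal", 1), class = "kgsearch_unknown_type")
  expect_error(make_node_id("article", "article/pmid/1"),
               class = "kgsearch_invalid_input")
  expect_identical(node_type_of(c("article/pmid/5", "bioentity/drug/9")),
                   c("article", "drug"))
})

test_that("metadata rows become the expected triples", {
  tabs <- list(
    authors = data.frame(pmid = 86509, aid = 6754, name = "x"),
    mentions = data.frame(pmid = 78456, entity_id = 1256, entity_type = "drug",
                          mention = "aspirin"),
    references = data.frame(pmid = 652148, cited_pmid = 415923),
    projects = data.frame(pmid = 5678, project_id = 4123)
  )
  tr <- build_triples(tabs)
  expect_identical(
    unname(as.matrix(tr[tr$relation == "article-writtenBy-author", ])),
    matrix(c("article/pmid/86509", "article-writtenBy-author", "author/aid/6754"), 1))
  expect_identical(
    unname(as.matrix(tr[tr$relation == "article-mentions-drug", ])),
    matrix(c("bioentity/drug/1256", "article-mentions-drug", "article/pmid/78456"), 1))
  expect_identical(
    unname(as.matrix(tr[tr$relation == "article-isFundedBy-NIHProject", ])),
    matrix(c("article/pmid/5678", "article-isFundedBy-NIHProject",
             "nih_project/project_id/4123"), 1))
  expect_equal(nrow(tr), 4)

  expect_equal(nrow(build_triples(list())), 0)

  # unparseable entity type: row skipped and reported
  bad <- list(mentions = data.frame(pmid = c(1, 2), entity_id = c(3, 4),
                                    entity_type = c("drug", "mineral"),
                                    mention = c("a", "b")))
  tr2 <- build_triples(bad)
  expect_equal(nrow(tr2), 1)
  expect_length(attr(tr2, "row_errors"), 1)

  # duplicated rows collapse before triple emission
  dup <- list(authors = data.frame(pmid = c(1, 1), aid = c(2, 2), name = "x"))
  expect_equal(nrow(build_triples(dup)), 1)
})

test_that("graph assembly collapses duplicates and counts check out", {
  one <- data.frame(head = "article/pmid/1", relation = "article-cites-article",
                    tail = "article/pmid/2")
  g1 <- assemble_graph(one)
  expect_equal(igraph::vcount(g1), 2)
  expect_equal(igraph::ecount(g1), 1)

  # the four worked authorship/mention/funding/citation triples: eight
  # distinct node ids, four edges, four labels (hand enumeration)
  four <- data.frame(
    head = c("article/pmid/86509", "bioentity/drug/1256", "article/pmid/5678",
             "article/pmid/652148"),
    relation = c("article-writtenBy-author", "article-mentions-drug",
                 "article-isFundedBy-NIHProject", "article-cites-article"),
    tail = c("author/aid/6754", "article/pmid/78456",
             "nih_project/project_id/4123", "article/pmid/415923"))
  g4 <- assemble_graph(four)
  expect_equal(igraph::vcount(g4), 8)
  expect_equal(igraph::ecount(g4), 4)
  expect_equal(length(unique(igraph::E(g4)$label)), 4)

  # same pair + label in either orientation collapses to one undirected edge
  dup <- rbind(one, data.frame(head = "article/pmid/2",
                               relation = "article-cites-article",
                               tail = "article/pmid/1"))
  expect_equal(igraph::ecount(assemble_graph(dup)), 1)

  expect_error(assemble_graph(data.frame(head = "a", relation = "nope", tail = "b")),
               class = "kgsearch_invalid_input")
})

test_that("node count equals the brute-force distinct-id union over tables", {
  tb <- generate_tables(synth_config(n_articles = 50, n_topics = 3, seed = 3))
  g <- assemble_graph(build_triples(tb))
  expected <- unique(c(
    make_node_id("article", tb$articles$pmid),
    make_node_id("author", unique(tb$authors$aid)),
    make_node_id(tb$mentions$entity_type, tb$mentions$entity_id),
    make_node_id("article", tb$references$cited_pmid),
    make_node_id("nih_project", unique(tb$projects$project_id)),
    make_node_id("mesh_term", unique(tb$mesh$header_id))))
  expect_equal(igraph::vcount(g), length(expected))
  expect_setequal(igraph::V(g)$name, expected)

  # type partition and label partition sum to the totals
  s <- kg_summary(g)
  expect_equal(sum(s$nodes[-1]), unname(s$nodes["total"]))
  expect_equal(sum(s$edges[-1]), unname(s$edges["total"]))
})

test_that("first-order citation closure enumerates adjacency", {
  tabs <- list(references = data.frame(pmid = c(1, 3, 2),
                                       cited_pmid = c(2, 1, 4)))
  expect_identical(citation_closure(tabs, integer(0)), integer(0))
  expect_identical(citation_closure(tabs, 1), c(1L, 2L, 3L))
  all_p <- citation_closure(tabs, 1:4)
  expect_identical(all_p, 1:4)
  expect_error(citation_closure(tabs, 1, order = 2),
               class = "kgsearch_invalid_input")
})

test_that("the entity index unifies variant mentions under one identifier", {
  empty <- build_entity_index(data.frame(pmid = integer(0), entity_id = integer(0),
                                         entity_type = character(0),
                                         mention = character(0)))
  expect_equal(nrow(empty$mentions), 0)

  idx <- build_entity_index(data.frame(
    pmid = c(1, 2, 2), entity_id = c(9, 9, 11),
    entity_type = c("drug", "drug", "disease"),
    mention = c("Aspirin", "aspirin", "Flu!")))
  expect_equal(nrow(idx$mentions), 2)  # "aspirin" and "flu"
  expect_identical(idx$mentions$mention[idx$mentions$entity_id == 9], "aspirin")
  expect_identical(idx$articles[["9"]], c(1, 2))
  expect_identical(idx$articles[["11"]], 2)

  skipped <- build_entity_index(data.frame(
    pmid = 1, entity_id = 5, entity_type = "mineral", mention = "salt"))
  expect_equal(nrow(skipped$mentions), 0)
  expect_length(attr(skipped, "row_errors"), 1)
})

test_that("the graph round-trips through node/edge list files", {
  tb <- generate_tables(synth_config(n_articles = 25, n_topics = 2, seed = 4))
  g <- assemble_graph(build_triples(tb))
  dir <- withr::local_tempdir()
  write_kg(g, dir)
  g2 <- read_kg(dir)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  el <- function(x) {
    e <- igraph::as_edgelist(x)
    df <- data.frame(a = pmin(e[, 1], e[, 2]), b = pmax(e[, 1], e[, 2]),
                     l = igraph::E(x)$label)
    df[order(df$a, df$b, df$l), ]
  }
  expect_equal(el(g2), el(g), ignore_attr = TRUE)
})
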