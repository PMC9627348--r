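make_square_graph <- function() {
  # edges A-B, B-C, A-C, B-D
  g <- igraph::graph_from_edgelist(
    rbind(c("A", "B"), c("B", "C"), c("A", "C"), c("B", "D")), directed = FALSE)
  igraph::V(g)$type <- "article"
  g
}

test_that("second-order transition probabilities follow the p/q weights", {
  g <- make_square_graph()
  d <- transition_distribution(g, prev = "A", cur = "B", p = 2, q = 0.5)
  expect_equal(d, c(A = 1 / 7, C = 2 / 7, D = 4 / 7))

  first <- transition_distribution(g, prev = NULL, cur = "B", p = 2, q = 0.5)
  expect_equal(unname(first), rep(1 / 3, 3))

  unb <- transition_distribution(g, prev = "A", cur = "B", p = 1, q = 1)
  expect_equal(unname(unb), rep(1 / 3, 3))
})

test_that("transition distributions match the shortest-path oracle on random graphs", {
  for (case in list(c(12, 0.3, 11), c(30, 0.15, 12), c(50, 0.08, 13))) {
    g <- random_named_graph(case[1], case[2], seed = case[3])
    el <- igraph::as_edgelist(g)
    for (r in seq_len(nrow(el))) {
      for (ori in 1:2) {
        prev <- el[r, ori]; cur <- el[r, 3 - ori]
        got <- transition_distribution(g, prev, cur, p = 2, q = 0.5)
        expect_equal(got, trans_oracle(g, prev, cur, p = 2, q = 0.5),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("sampled walks are valid paths and deterministic", {
  tb <- generate_tables(synth_config(n_articles = 40, n_topics = 2, seed = 6))
  g <- assemble_graph(build_triples(tb))
  cfg <- embedding_config(dim = 16, walk_length = 20, walks_per_node = 3, seed = 5)
  corpus <- sample_walks(g, cfg)
  expect_equal(length(corpus$walks), 3 * igraph::vcount(g))
  seqs <- walk_sequences(corpus)
  for (w in seqs[seq(1, length(seqs), by = 7)]) {
    if (length(w) < 2) next
    for (i in seq_len(length(w) - 1)) {
      expect_true(igraph::are_adjacent(g, w[i], w[i + 1]))
    }
  }
  expect_identical(corpus$walks, sample_walks(g, cfg)$walks)
  cfg2 <- cfg; cfg2$seed <- 6L
  expect_false(identical(corpus$walks, sample_walks(g, cfg2)$walks))
})

test_that("dead ends truncate walks and degenerate lengths behave", {
  iso <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices("solo")
  igraph::V(iso)$type <- "article"
  cfg <- embedding_config(dim = 4, walk_length = 50, walks_per_node = 2, seed = 1)
  corpus <- sample_walks(iso, cfg)
  expect_true(all(lengths(corpus$walks) == 1))

  two <- igraph::graph_from_edgelist(rbind(c("x", "y")), directed = FALSE)
  igraph::V(two)$type <- "article"
  w <- walk_sequences(sample_walks(two, embedding_config(
    dim = 4, walk_length = 9, walks_per_node = 2, p = 3, q = 0.2, seed = 2)))
  for (s in w) {
    expect_equal(length(s), 9)
    expect_true(all(s[seq(1, 9, 2)] == s[1]))  # strict alternation on a path
  }

  w1 <- sample_walks(two, embedding_config(dim = 4, walk_length = 1,
                                           walks_per_node = 2, seed = 3))
  expect_true(all(lengths(w1$walks) == 1))
})

test_that("first transition is empirically uniform over neighbors", {
  g <- make_square_graph()
  cfg <- embedding_config(dim = 4, walk_length = 2, walks_per_node = 3000, seed = 11)
  seqs <- walk_sequences(sample_walks(g, cfg))
  from_b <- vapply(seqs[vapply(seqs, `[`, "", 1) == "B"], `[`, "", 2)
  freq <- table(from_b) / length(from_b)
  expect_equal(unname(as.numeric(freq)), rep(1 / 3, 3), tolerance = 0.05)
})

test_that("negative-sampling objective matches closed forms at zero parameters", {
  vocab <- c("a", "b", "c", "d")
  zero <- list(input = matrix(0, 4, 3, dimnames = list(vocab, NULL)),
               output = matrix(0, 4, 3, dimnames = list(vocab, NULL)))
  expect_equal(negative_sampling_loss("a", "b", "c", zero), 2 * log(0.5))
  expect_equal(negative_sampling_loss("a", "b", rep(c("c", "d"), c(4, 3)), zero),
               8 * log(0.5))
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  vocab <- letters[1:6]
  for (rep in 1:5) {
    params <- list(
      input = matrix(rnorm(6 * 5, sd = 0.5), 6, 5, dimnames = list(vocab, NULL)),
      output = matrix(rnorm(6 * 5, sd = 0.5), 6, 5, dimnames = list(vocab, NULL)))
    center <- "a"; context <- "b"; negs <- c("c", "d", "e")
    gr <- sgns_gradient(center, context, negs, params)
    h <- 1e-5
    num_grad <- function(get, set) {
      vapply(seq_len(5), function(k) {
        pp <- params; pm <- params
        pp <- set(pp, k, h); pm <- set(pm, k, -h)
        (negative_sampling_loss(center, context, negs, pp) -
         negative_sampling_loss(center, context, negs, pm)) / (2 * h)
      }, 1)
    }
    rel_err <- function(a, b) max(abs(a - b) / pmax(abs(a) + abs(b), 1e-8))
    n_c <- num_grad(NULL, function(p, k, d) { p$input[center, k] <- p$input[center, k] + d; p })
    expect_lt(rel_err(gr$d_center, n_c), 1e-5)
    n_o <- num_grad(NULL, function(p, k, d) { p$output[context, k] <- p$output[context, k] + d; p })
    expect_lt(rel_err(gr$d_context, n_o), 1e-5)
    n_j <- num_grad(NULL, function(p, k, d) { p$output["c", k] <- p$output["c", k] + d; p })
    expect_lt(rel_err(gr$d_negatives[[1]], n_j), 1e-5)
  }
})

test_that("training is deterministic and covers the vocabulary", {
  g <- barbell_graph()
  cfg <- embedding_config(dim = 8, window = 3, walk_length = 15,
                          walks_per_node = 5, epochs = 10, seed = 4)
  corpus <- sample_walks(g, cfg)
  e1 <- train_skipgram(corpus, cfg)
  e2 <- train_skipgram(corpus, cfg)
  expect_identical(e1, e2)
  expect_setequal(rownames(e1), igraph::V(g)$name)
  expect_equal(ncol(e1), 8)
  expect_true(all(is.finite(e1)))

  # single-node corpus: one vocabulary entry, d columns, finite values
  iso <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices("solo")
  igraph::V(iso)$type <- "article"
  ei <- train_skipgram(sample_walks(iso, cfg), cfg)
  expect_equal(dim(ei), c(1, 8))
  expect_true(all(is.finite(ei)))
})

test_that("embeddings round-trip through word2vec text format", {
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("article/pmid/1", "author/aid/2", "bioentity/drug/3"), NULL))
  path <- withr::local_tempfile(fileext = ".w2v")
  write_word2vec(m, path)
  back <- read_word2vec(path)
  expect_equal(back, m, tolerance = 1e-7)
  expect_identical(readLines(path, n = 1), "3 4")
})
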