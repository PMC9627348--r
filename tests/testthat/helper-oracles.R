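# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: full DP matrices, dense linear algebra, shortest-path
# lookups -- different code paths from the functions they verify.

# Levenshtein distance by the full dynamic-programming matrix.
lev_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  D <- matrix(0L, n + 1, m + 1)
  D[, 1] <- 0:n; D[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- min(D[i, j + 1] + 1L, D[i + 1, j] + 1L,
                             D[i, j] + (ca[i] != cb[j]))
    }
  }
  D[n + 1, m + 1]
}

# Second-order walk transition probabilities via shortest-path distances from
# the previous node: weight 1/p at distance 0 (return), 1 at distance 1,
# 1/q at distance 2.
trans_oracle <- function(graph, prev, cur, p, q) {
  nbrs <- sort(igraph::V(graph)$name[
    unique(as.integer(igraph::neighbors(graph, cur)))])
  if (length(nbrs) == 0) return(setNames(numeric(0), character(0)))
  if (is.null(prev)) return(setNames(rep(1 / length(nbrs), length(nbrs)), nbrs))
  d <- igraph::distances(graph, v = prev, to = nbrs)[1, ]
  w <- ifelse(d == 0, 1 / p, ifelse(d == 1, 1, 1 / q))
  setNames(w / sum(w), nbrs)
}

# Position-by-position retrieval metrics.
prf_oracle <- function(retrieved, relevant, k) {
  top <- retrieved[seq_len(min(k, length(retrieved)))]
  r <- sum(top %in% relevant)
  p <- if (length(top) == 0) 0 else r / length(top)
  rec <- r / length(unique(relevant))
  f1 <- if (p + rec == 0) 0 else 2 * p * rec / (p + rec)
  c(precision = p, recall = rec, f1 = f1)
}

ap_oracle <- function(retrieved, relevant, k, variant = "standard") {
  top <- retrieved[seq_len(min(k, length(retrieved)))]
  if (length(top) == 0) return(0)
  prec <- vapply(seq_along(top), function(i)
    sum(top[1:i] %in% relevant) / i, 1)
  if (variant == "standard") {
    hit <- top %in% relevant
    if (!any(hit)) return(0)
    sum(prec[hit]) / min(length(unique(relevant)), k)
  } else {
    mean(prec)
  }
}

# Dense tf-idf document matrix: tf * log(N/df), rows L2-normalized.
tfidf_oracle <- function(corpus) {
  vocab <- sort(unique(unlist(corpus)))
  N <- length(corpus)
  tf <- t(vapply(corpus, function(tok)
    vapply(vocab, function(v) sum(tok == v), 1), numeric(length(vocab))))
  df <- colSums(tf > 0)
  w <- tf * rep(log(N / df), each = N)
  norms <- sqrt(rowSums(w^2))
  norms[norms == 0] <- 1
  out <- w / norms
  dimnames(out) <- list(names(corpus), vocab)
  out
}

# Small labeled KG built from explicit edge pairs, for pooling tests.
toy_graph <- function(edges, types) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = names(types),
                                                           type = unname(types)))
  g
}

# Random simple graph with named vertices (no isolated-vertex guarantee).
random_named_graph <- function(n, p_edge, seed) {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p_edge))
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  igraph::V(g)$type <- "article"
  g
}

# Hub with `n_arms` paths of `arm_len` nodes each, for the depth-bias check.
star_of_paths <- function(n_arms = 6, arm_len = 8) {
  edges <- NULL
  for (a in seq_len(n_arms)) {
    chain <- c("hub", sprintf("a%d_%d", a, seq_len(arm_len)))
    edges <- rbind(edges, cbind(chain[-length(chain)], chain[-1]))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$type <- "article"
  g
}

# Two K4 cliques joined by one bridge.
barbell_graph <- function() {
  left <- t(combn(paste0("L", 1:4), 2))
  right <- t(combn(paste0("R", 1:4), 2))
  g <- igraph::graph_from_edgelist(rbind(left, right, c("L1", "R1")),
                                   directed = FALSE)
  igraph::V(g)$type <- "article"
  g
}

mean_pairwise_cos <- function(emb, a, b = a) {
  vals <- c()
  for (x in a) for (y in b) {
    if (x == y) next
    vals <- c(vals, cosine_sim(emb[x, ], emb[y, ]))
  }
  mean(vals)
}
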