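# Node embeddings: p/q-biased second-order random walks over the knowledge
# graph followed by skip-gram with negative sampling.
#
# The walk is second-order: having stepped prev -> cur, the unnormalized
# probability of moving to neighbor x of cur is 1/p if x == prev (return),
# 1 if x is also a neighbor of prev (stay close), and 1/q otherwise (move
# away). q < 1 therefore biases walks outward, depth-first style; q > 1 keeps
# them local, breadth-first style.

#' Embedding hyperparameters
#'
#' Defaults are the tuned operating point used throughout the package:
#' 128-dimensional vectors, context window 5, 7 negative samples, return bias
#' p = 2, in-out bias q = 0.5, walks of 50 nodes, 5 walks per node.
#'
#' @param dim vector dimension d.
#' @param window context radius in walk positions.
#' @param negatives noise samples per positive (center, context) pair.
#' @param p return-bias parameter (> 0); larger p discourages revisiting the
#'   previous node.
#' @param q in-out bias parameter (> 0); q < 1 pushes walks away from the
#'   start node.
#' @param walk_length nodes per walk.
#' @param walks_per_node walks started from every node.
#' @param epochs passes of skip-gram training over the walk corpus.
#' @param alpha,alpha_min initial and floor learning rate (linear decay).
#' @param noise_exponent exponent of the unigram noise distribution
#'   P(v) proportional to freq(v)^noise_exponent.
#' @param seed integer seed controlling walks and training.
#' @return validated `embedding_config` list.
#' @export
embedding_config <- function(dim = 128, window = 5, negatives = 7, p = 2,
                             q = 0.5, walk_length = 50, walks_per_node = 5,
                             epochs = 5, alpha = 0.025, alpha_min = 1e-4,
                             noise_exponent = 0.75, seed = 1L) {
  cfg <- list(dim = as.integer(dim), window = as.integer(window),
              negatives = as.integer(negatives), p = p, q = q,
              walk_length = as.integer(walk_length),
              walks_per_node = as.integer(walks_per_node),
              epochs = as.integer(epochs), alpha = alpha,
              alpha_min = alpha_min, noise_exponent = noise_exponent,
              seed = as.integer(seed))
  stopifnot(cfg$dim >= 1, cfg$window >= 1, cfg$negatives >= 0, cfg$p > 0,
            cfg$q > 0, cfg$walk_length >= 1, cfg$walks_per_node >= 1,
            cfg$epochs >= 1, cfg$alpha > 0)
  class(cfg) <- "embedding_config"
  cfg
}

# sorted 0-based CSR adjacency of the (simple) neighbor structure
graph_adjacency <- function(graph) {
  adj <- igraph::as_adj_list(graph, mode = "all")
  adj <- lapply(adj, function(v) sort(unique(as.integer(v) - 1L)))
  list(offsets = c(0L, cumsum(vapply(adj, length, 1L))),
       neighbors = as.integer(unlist(adj, use.names = FALSE)))
}

#' Second-order transition distribution of the biased walk
#'
#' Reference implementation used for verification; the walker reproduces it.
#'
#' @param graph knowledge graph.
#' @param prev previous node id, or `NULL` on the first step (uniform over
#'   neighbors of `cur`).
#' @param cur current node id.
#' @param p,q bias parameters.
#' @return named numeric vector of probabilities over the neighbors of `cur`
#'   (empty if `cur` is isolated).
#' @export
transition_distribution <- function(graph, prev, cur, p, q) {
  nbrs <- sort(unique(igraph::V(graph)$name[
    as.integer(igraph::neighbors(graph, cur, mode = "all"))]))
  if (length(nbrs) == 0) return(stats::setNames(numeric(0), character(0)))
  if (is.null(prev)) {
    w <- rep(1, length(nbrs))
  } else {
    prev_nbrs <- igraph::V(graph)$name[
      as.integer(igraph::neighbors(graph, prev, mode = "all"))]
    w <- vapply(nbrs, function(x) {
      if (x == prev) 1 / p
      else if (x %in% prev_nbrs) 1
      else 1 / q
    }, 1)
  }
  stats::setNames(w / sum(w), nbrs)
}

#' Sample a corpus of biased random walks
#'
#' Starts `walks_per_node` walks at every node of the graph; each walk has at
#' most `walk_length` nodes and is shorter only at a dead end (isolated node).
#' Deterministic given the config seed.
#'
#' @param graph knowledge graph.
#' @param config an [embedding_config()].
#' @return a `walk_corpus`: list with `walks` (list of integer vectors,
#'   1-based vertex indices), `vocab` (vertex names) and `n_tokens`.
#' @export
sample_walks <- function(graph, config) {
  if (igraph::vcount(graph) == 0)
    stop_with("kgsearch_invalid_input", "graph is empty")
  adj <- graph_adjacency(graph)
  walks <- cpp_sample_walks(adj$offsets, adj$neighbors, config$p, config$q,
                            config$walk_length, config$walks_per_node,
                            config$seed)
  structure(list(walks = walks, vocab = igraph::V(graph)$name,
                 n_tokens = sum(lengths(walks))),
            class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat("walk corpus:", length(x$walks), "walks,", x$n_tokens, "tokens over",
      length(x$vocab), "nodes\n")
  invisible(x)
}

#' Walks as node-id sequences
#' @param corpus a `walk_corpus`.
#' @return list of character vectors.
#' @export
walk_sequences <- function(corpus) {
  lapply(corpus$walks, function(w) corpus$vocab[w])
}

#' Skip-gram negative-sampling objective for one training example
#'
#' The per-pair objective log sigma(u_o . v_c) + sum_j log sigma(-u_j . v_c),
#' maximized during training (the trainer ascends its gradient).
#'
#' @param center,context node ids (rows of the parameter matrices).
#' @param negatives character vector of noise node ids.
#' @param params list with `input` and `output` matrices (vocab x dim,
#'   rownames = node ids).
#' @return scalar objective value (<= 0).
#' @export
negative_sampling_loss <- function(center, context, negatives, params) {
  vc <- params$input[center, ]
  uo <- params$output[context, ]
  val <- log_sigmoid(sum(uo * vc))
  for (j in negatives) val <- val + log_sigmoid(-sum(params$output[j, ] * vc))
  val
}

log_sigmoid <- function(x) -log1p(exp(-x))

#' Analytic gradient of the negative-sampling objective
#'
#' @inheritParams negative_sampling_loss
#' @return list with `d_center` (gradient wrt v_c), `d_context` (wrt u_o) and
#'   `d_negatives` (list, wrt each u_j).
#' @export
sgns_gradient <- function(center, context, negatives, params) {
  vc <- params$input[center, ]
  uo <- params$output[context, ]
  s_pos <- 1 / (1 + exp(sum(uo * vc)))         # 1 - sigma(uo.vc)
  d_center <- s_pos * uo
  d_context <- s_pos * vc
  d_neg <- vector("list", length(negatives))
  for (i in seq_along(negatives)) {
    uj <- params$output[negatives[i], ]
    s_neg <- 1 / (1 + exp(-sum(uj * vc)))      # sigma(uj.vc)
    d_center <- d_center - s_neg * uj
    d_neg[[i]] <- -s_neg * vc
  }
  list(d_center = d_center, d_context = d_context, d_negatives = d_neg)
}

#' Train skip-gram node embeddings on a walk corpus
#'
#' Every in-window pair of walk positions is a positive example; `negatives`
#' noise nodes are drawn per pair from the unigram distribution raised to
#' `noise_exponent`. Stochastic gradient ascent with a linearly decaying
#' learning rate; single-threaded and deterministic for a given seed.
#'
#' @param corpus a `walk_corpus` from [sample_walks()].
#' @param config an [embedding_config()].
#' @return numeric matrix, one row per vocabulary node (rownames = node ids),
#'   `config$dim` columns: the released input vectors.
#' @export
train_skipgram <- function(corpus, config) {
  if (length(corpus$walks) == 0 || length(corpus$vocab) == 0)
    stop_with("kgsearch_invalid_input", "walk corpus has an empty vocabulary")
  vocab_size <- length(corpus$vocab)
  counts <- tabulate(unlist(corpus$walks, use.names = FALSE), nbins = vocab_size)
  w <- counts^config$noise_exponent
  if (sum(w) == 0) w <- rep(1, vocab_size)
  noise_cdf <- cumsum(w / sum(w))
  noise_cdf[vocab_size] <- 1  # guard against rounding
  emb <- cpp_train_sgns(corpus$walks, vocab_size, config$dim, config$window,
                        config$negatives, config$epochs, config$alpha,
                        config$alpha_min, noise_cdf, config$seed + 1)
  rownames(emb) <- corpus$vocab
  emb
}

#' Write embeddings in word2vec text format
#'
#' First line `<vocab> <dim>`, then one `<node-id> <d floats>` line per node.
#' @param emb matrix with rownames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(emb, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(nrow(emb), ncol(emb)), con)
  body <- vapply(seq_len(nrow(emb)), function(i)
    paste(rownames(emb)[i], paste(sprintf("%.8g", emb[i, ]), collapse = " ")), "")
  writeLines(body, con)
  invisible(path)
}

#' Read embeddings from word2vec text format
#' @param path file written by [write_word2vec()].
#' @return matrix with rownames.
#' @export
read_word2vec <- function(path) {
  if (!file.exists(path))
    stop_with("kgsearch_missing_artifact", paste("missing vector file:", path))
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  n <- hdr[1]; d <- hdr[2]
  parts <- strsplit(lines[1 + seq_len(n)], " ", fixed = TRUE)
  emb <- matrix(0, n, d)
  nms <- character(n)
  for (i in seq_len(n)) {
    nms[i] <- parts[[i]][1]
    emb[i, ] <- as.numeric(parts[[i]][-1])
  }
  rownames(emb) <- nms
  emb
}
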