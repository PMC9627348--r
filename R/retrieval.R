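# Article and query vectors, cosine ranking, and the end-to-end search path.
#
# Article vectors are built in two stages: stage 1 averages the raw node
# vectors of ALL first-order neighbors of every article (authors, entities,
# MeSH terms, projects, other articles); stage 2 averages, for each target
# article, the stage-1 vectors of its first-order article (citation)
# neighbors, falling back to the article's own stage-1 vector when it has no
# citation neighbors. Query vectors average the raw node vectors of the
# matched bio-entities.

#' Mean-pool the vectors of a node's first-order neighbors
#'
#' @param graph knowledge graph.
#' @param vectors matrix of vectors, rownames = node ids.
#' @param node node id.
#' @param neighbor_types optional character vector restricting pooled
#'   neighbors to these node types (`NULL` = all types).
#' @param include_self also include the node's own vector in the mean.
#' @return numeric d-vector.
#' @export
pool_neighbors <- function(graph, vectors, node, neighbor_types = NULL,
                           include_self = FALSE) {
  nb <- unique(as.integer(igraph::neighbors(graph, node, mode = "all")))
  ids <- igraph::V(graph)$name[nb]
  if (!is.null(neighbor_types)) {
    keep <- igraph::V(graph)$type[nb] %in% neighbor_types
    ids <- ids[keep]
  }
  if (include_self) ids <- c(ids, node)
  ids <- ids[ids %in% rownames(vectors)]
  if (length(ids) == 0)
    stop_with("kgsearch_undefined_vector",
              paste("no vectors to pool for node", node))
  colMeans(vectors[ids, , drop = FALSE])
}

#' Two-stage pooled article vectors
#'
#' @param graph knowledge graph.
#' @param emb node embedding matrix from [train_skipgram()].
#' @param targets integer pmids searchable at query time (default: all
#'   article nodes in the graph).
#' @return an `article_vectors` object: list with `stage1` (all articles),
#'   `stage2` (targets only), `targets`, `dim`. Row names are article node
#'   ids.
#' @export
article_embeddings <- function(graph, emb, targets = NULL) {
  v_names <- igraph::V(graph)$name
  art <- v_names[igraph::V(graph)$type == "article"]
  if (is.null(targets)) targets <- sort(pmid_of(art))
  tgt_ids <- make_node_id("article", targets)
  missing <- setdiff(tgt_ids, art)
  if (length(missing) > 0)
    stop_with("kgsearch_missing_target",
              paste("target pmids not in graph:", paste(missing, collapse = ", ")))

  stage1 <- matrix(0, length(art), ncol(emb), dimnames = list(art, NULL))
  for (a in art) {
    stage1[a, ] <- tryCatch(
      pool_neighbors(graph, emb, a),
      kgsearch_undefined_vector = function(e) emb[a, ]  # isolated article
    )
  }
  stage2 <- matrix(0, length(tgt_ids), ncol(emb), dimnames = list(tgt_ids, NULL))
  for (a in tgt_ids) {
    stage2[a, ] <- tryCatch(
      pool_neighbors(graph, stage1, a, neighbor_types = "article"),
      kgsearch_undefined_vector = function(e) stage1[a, ]  # uncited article
    )
  }
  structure(list(stage1 = stage1, stage2 = stage2, targets = sort(targets),
                 dim = ncol(emb)),
            class = "article_vectors")
}

#' @export
print.article_vectors <- function(x, ...) {
  cat("article vectors: stage1 x", nrow(x$stage1), ", stage2 x",
      nrow(x$stage2), ", dim", x$dim, "\n")
  invisible(x)
}

#' Query vector from matched entities
#'
#' Averages the raw knowledge-graph node vectors of the matched bio-entities.
#'
#' @param match a `match_set` from [match_query()].
#' @param emb node embedding matrix.
#' @return numeric d-vector.
#' @export
embed_query <- function(match, emb) {
  if (!inherits(match, "match_set") || nrow(match$matched) == 0)
    stop_with("kgsearch_no_match", "no keywords matched the entity index")
  ids <- make_node_id(match$matched$entity_type, match$matched$entity_id)
  absent <- setdiff(ids, rownames(emb))
  if (length(absent) > 0)
    stop_with("kgsearch_missing_node",
              paste("matched entities without KG vectors:",
                    paste(absent, collapse = ", ")))
  colMeans(emb[ids, , drop = FALSE])
}

#' Cosine similarity of two vectors
#'
#' @param a,b numeric vectors of equal length; both must be nonzero.
#' @return scalar in \[-1, 1\].
#' @export
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop_with("kgsearch_zero_vector", "cosine of a zero vector is undefined")
  sum(a * b) / (na * nb)
}

#' Rank target articles by cosine similarity to a query vector
#'
#' Scores all target (stage-2) article vectors, sorts by descending score with
#' ties broken by ascending pmid, and truncates to `k`.
#'
#' @param query_vec numeric d-vector.
#' @param art_vecs an `article_vectors` object.
#' @param k cutoff (use `Inf` for the full ranking).
#' @return a `ranked_result` data.frame (rank, pmid, score).
#' @export
rank_articles <- function(query_vec, art_vecs, k = 10) {
  stopifnot(k >= 1)
  m <- art_vecs$stage2
  if (nrow(m) == 0)
    return(structure(data.frame(rank = integer(0), pmid = integer(0),
                                score = numeric(0)),
                     class = c("ranked_result", "data.frame")))
  qn <- sqrt(sum(query_vec^2))
  if (qn == 0) stop_with("kgsearch_zero_vector", "query vector is zero")
  norms <- sqrt(rowSums(m^2))
  scores <- as.numeric(m %*% query_vec) / (norms * qn)
  scores[norms == 0] <- -Inf  # degenerate article vectors rank last
  pmids <- pmid_of(rownames(m))
  ord <- order(-scores, pmids)
  n <- min(length(ord), k)
  out <- data.frame(rank = seq_len(n), pmid = pmids[ord[seq_len(n)]],
                    score = scores[ord[seq_len(n)]])
  class(out) <- c("ranked_result", "data.frame")
  out
}

#' End-to-end semantic search
#'
#' Runs tokenize -> expand -> match -> embed -> rank against a loaded system
#' state and records each stage's intermediate sizes.
#'
#' @param text free-text query.
#' @param state list with components `graph`, `index`, `emb`, `art_vecs`
#'   (as produced by [run_pipeline()] or [load_state()]).
#' @param k cutoff for the returned ranking.
#' @param windows sliding-window sizes for expansion.
#' @param max_distance Levenshtein threshold for entity matching.
#' @param stopwords stop-word list for tokenization.
#' @return a `ranked_result` with a `"log"` attribute, or a `search_no_match`
#'   object (empty result, `status = "no_match"`) when no keyword matches the
#'   index.
#' @export
kg_search <- function(text, state, k = 10, windows = c(2L, 3L, 4L),
                      max_distance = 1L, stopwords = DEFAULT_STOPWORDS) {
  tq <- tokenize_query(text, stopwords = stopwords)
  kws <- expand_query(tq, windows = windows)
  ms <- match_query(kws, state$index, max_distance = max_distance)
  log <- list(tokens = length(tq$tokens), keywords = length(kws),
              matched_entities = nrow(ms$matched),
              unmatched_keywords = length(ms$unmatched))
  if (nrow(ms$matched) == 0) {
    return(structure(list(status = "no_match", query = text, log = log),
                     class = "search_no_match"))
  }
  qv <- embed_query(ms, state$emb)
  res <- rank_articles(qv, state$art_vecs, k = k)
  log$ranked <- nrow(res)
  attr(res, "log") <- log
  attr(res, "match") <- ms
  res
}

#' @export
print.search_no_match <- function(x, ...) {
  cat("no results: no query keyword matched the entity index\n")
  invisible(x)
}
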