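# Bag-of-words TF-IDF baseline ranker over article text.

tokenize_text <- function(x) {
  strsplit(trimws(tolower(x)), "[[:space:]]+")
}

#' Fit a TF-IDF model on an article corpus
#'
#' Term frequency is the raw within-document count; idf(term) = log(N / df);
#' document vectors are tf x idf, L2-normalized. Zero-idf terms (present in
#' every document) are retained with weight zero; no add-one smoothing.
#'
#' @param corpus either a named list (names = pmids) of token character
#'   vectors, or an articles data.frame with `pmid`, `title`, `abstract`
#'   columns (title and abstract tokens concatenated).
#' @return a `tfidf_model`: list with `vocab`, `idf`, `dtm` (sparse docs x
#'   terms, rows L2-normalized) and `pmids`.
#' @export
fit_tfidf <- function(corpus) {
  if (is.data.frame(corpus)) {
    toks <- tokenize_text(paste(corpus$title, corpus$abstract))
    names(toks) <- corpus$pmid
    corpus <- toks
  }
  if (length(corpus) == 0)
    stop_with("kgsearch_invalid_input", "corpus is empty")
  pmids <- names(corpus)
  vocab <- sort(unique(unlist(corpus, use.names = FALSE)))
  vocab <- vocab[nchar(vocab) > 0]
  N <- length(corpus)
  df <- integer(length(vocab))
  names(df) <- vocab
  ijx <- lapply(seq_along(corpus), function(i) {
    tok <- corpus[[i]]
    tok <- tok[nchar(tok) > 0]
    if (length(tok) == 0) return(NULL)
    tf <- table(tok)
    data.frame(i = i, j = match(names(tf), vocab), x = as.numeric(tf))
  })
  ijx <- do.call(rbind, ijx)
  if (!is.null(ijx)) {
    dfc <- table(ijx$j)
    df[as.integer(names(dfc))] <- as.integer(dfc)
  }
  idf <- log(N / pmax(df, 1))
  idf[df == 0] <- 0
  tfm <- Matrix::sparseMatrix(i = if (is.null(ijx)) integer(0) else ijx$i,
                              j = if (is.null(ijx)) integer(0) else ijx$j,
                              x = if (is.null(ijx)) numeric(0) else ijx$x,
                              dims = c(N, length(vocab)),
                              dimnames = list(pmids, vocab))
  w <- tfm %*% Matrix::Diagonal(x = idf)
  norms <- sqrt(Matrix::rowSums(w^2))
  norms[norms == 0] <- 1  # empty/zero documents stay zero vectors
  dtm <- Matrix::Diagonal(x = 1 / norms) %*% w
  dimnames(dtm) <- list(pmids, vocab)
  structure(list(vocab = vocab, idf = stats::setNames(idf, vocab), dtm = dtm,
                 pmids = pmids),
            class = "tfidf_model")
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat("tf-idf model:", length(x$pmids), "documents,", length(x$vocab), "terms\n")
  invisible(x)
}

#' Rank documents against a query with a fitted TF-IDF model
#'
#' The query is vectorized with the model's idf weights and compared to every
#' document by cosine; ties break by ascending pmid, as in the embedding
#' ranker.
#'
#' @param query_tokens character vector of query tokens (or a raw string,
#'   which is whitespace-tokenized after lower-casing).
#' @param model a `tfidf_model`.
#' @param k cutoff (use `Inf` for the full ranking).
#' @return a `ranked_result` data.frame (rank, pmid, score); empty when the
#'   query is fully out of vocabulary.
#' @export
tfidf_rank <- function(query_tokens, model, k = 10) {
  stopifnot(inherits(model, "tfidf_model"), k >= 1)
  if (length(query_tokens) == 1 && grepl("[[:space:]]", query_tokens))
    query_tokens <- tokenize_text(query_tokens)[[1]]
  query_tokens <- tolower(query_tokens)
  j <- match(query_tokens, model$vocab)
  j <- j[!is.na(j)]
  empty <- structure(data.frame(rank = integer(0), pmid = integer(0),
                                score = numeric(0)),
                     class = c("ranked_result", "data.frame"))
  if (length(j) == 0) return(empty)
  q <- numeric(length(model$vocab))
  tf <- table(j)
  q[as.integer(names(tf))] <- as.numeric(tf) * model$idf[as.integer(names(tf))]
  qn <- sqrt(sum(q^2))
  if (qn == 0) return(empty)
  scores <- as.numeric(model$dtm %*% q) / qn  # rows already unit (or zero)
  pmids <- as.integer(model$pmids)
  ord <- order(-scores, pmids)
  n <- min(length(ord), k)
  out <- data.frame(rank = seq_len(n), pmid = pmids[ord[seq_len(n)]],
                    score = scores[ord[seq_len(n)]])
  class(out) <- c("ranked_result", "data.frame")
  out
}
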