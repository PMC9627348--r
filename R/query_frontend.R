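# Free-text query handling: tokenization, sliding-window expansion and fuzzy
# matching of keywords against the bio-entity index.

# Built-in default stop-word list: common English function words plus the
# query-scaffolding words users type at a search box ("show me articles
# on ..."), in the spirit of the stop lists shipped by mainstream IR
# toolkits. Configurable per call.
DEFAULT_STOPWORDS <- c(
  "a", "about", "above", "after", "again", "against", "all", "am", "an",
  "and", "any", "are", "as", "at", "be", "because", "been", "before",
  "being", "below", "between", "both", "but", "by", "can", "could", "did",
  "do", "does", "doing", "down", "during", "each", "few", "find", "for",
  "from", "further", "get", "give", "had", "has", "have", "having", "he",
  "her", "here", "hers", "him", "his", "how", "i", "if", "in", "into", "is",
  "it", "its", "just", "latest", "like", "look", "looking", "me", "more",
  "most", "my", "need", "new", "no", "nor", "not", "now", "of", "off", "on",
  "once", "only", "or", "other", "our", "ours", "out", "over", "own",
  "papers", "please", "recent", "related", "same", "search", "see", "she",
  "should", "show", "so", "some", "such", "tell", "than", "that", "the",
  "their", "theirs", "them", "then", "there", "these", "they", "this",
  "those", "through", "to", "too", "under", "until", "up", "very", "want",
  "was", "we", "were", "what", "when", "where", "which", "while", "who",
  "whom", "why", "will", "with", "would", "you", "your", "yours"
)

# Minimal lexicon for the optional verb filter (no part-of-speech tagger is
# bundled; this covers the imperative verbs seen in search queries).
DEFAULT_VERBS <- c(
  "show", "find", "give", "get", "want", "need", "see", "look", "search",
  "tell", "list", "display", "fetch", "retrieve", "bring", "help",
  "identify", "compare", "explain", "describe", "summarize", "return"
)

#' Tokenize a free-text query
#'
#' Lower-cases, strips punctuation, splits on whitespace, removes stop words
#' and (optionally) verbs. Token order is preserved.
#'
#' @param text query string; must be nonempty after whitespace stripping.
#' @param stopwords character vector of stop words to drop.
#' @param verb_filter when `TRUE`, also drop tokens in the built-in verb
#'   lexicon. Off by default.
#' @return a `tokenized_query`: list with `raw` and `tokens`. An all-stopword
#'   query yields an empty token list (downstream reports no match).
#' @export
tokenize_query <- function(text, stopwords = DEFAULT_STOPWORDS,
                           verb_filter = FALSE) {
  if (length(text) != 1 || is.na(text) || nchar(trimws(text)) == 0)
    stop_with("kgsearch_invalid_input", "query text is empty")
  x <- tolower(text)
  x <- gsub("[[:punct:]]+", " ", x)
  tokens <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  tokens <- tokens[!(tokens %in% stopwords)]
  if (verb_filter) tokens <- tokens[!(tokens %in% DEFAULT_VERBS)]
  structure(list(raw = text, tokens = tokens), class = "tokenized_query")
}

#' Expand tokens with sliding windows of n-grams
#'
#' The original tokens come first, then all contiguous w-grams (joined by a
#' single space) for each window size in ascending order, left to right
#' within a size. For n tokens and window set W the output length is
#' n + sum over w in W with w <= n of (n - w + 1).
#'
#' @param tq a `tokenized_query` (or plain character vector of tokens).
#' @param windows integer vector of window sizes; default `c(2, 3, 4)`.
#' @return character vector of keywords.
#' @export
expand_query <- function(tq, windows = c(2L, 3L, 4L)) {
  tokens <- if (inherits(tq, "tokenized_query")) tq$tokens else as.character(tq)
  n <- length(tokens)
  out <- tokens
  for (w in sort(unique(as.integer(windows)))) {
    if (w > n || w < 2) next
    for (i in seq_len(n - w + 1L))
      out <- c(out, paste(tokens[i:(i + w - 1L)], collapse = " "))
  }
  out
}

#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and substitutions
#' turning `a` into `b` (computed via the generalized edit distance in
#' [utils::adist()] with unit costs).
#'
#' @param a,b character vectors (recycled to a common length).
#' @return integer vector of distances.
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- integer(n)
  for (i in seq_len(n)) {
    out[i] <- as.integer(utils::adist(a[i], b[i],
                                      costs = list(ins = 1, del = 1, sub = 1)))
  }
  out
}

#' Match expanded keywords against the bio-entity index
#'
#' Each keyword is normalized like the index keys and compared to every
#' mention string by Levenshtein distance. A keyword matches the entity of
#' the minimum-distance mention when that distance is at or below
#' `max_distance`; ties go to the lexicographically smallest mention string
#' (then the smallest entity id). Duplicate entity ids across keywords
#' collapse to the first (smallest-distance) hit.
#'
#' @param keywords character vector from [expand_query()] (or a `MatchSet`
#'   precursor: any character vector).
#' @param index an `entity_index` from [build_entity_index()].
#' @param max_distance maximum edit distance accepted (default 1).
#' @return a `match_set`: list with `matched` (data.frame keyword, mention,
#'   entity_id, entity_type, distance) and `unmatched` (character vector).
#'   An empty `matched` table means the query cannot be served.
#' @export
match_query <- function(keywords, index, max_distance = 1L) {
  stopifnot(inherits(index, "entity_index"), max_distance >= 0)
  mm <- index$mentions
  hits <- list()
  unmatched <- character(0)
  for (kw in keywords) {
    key <- normalize_mention(kw)
    if (nchar(key) == 0) { unmatched <- c(unmatched, kw); next }
    exact <- which(mm$mention == key)
    if (length(exact) > 0) {
      i <- exact[order(mm$mention[exact], mm$entity_id[exact])][1]
      d <- 0L
    } else {
      dists <- utils::adist(key, mm$mention,
                            costs = list(ins = 1, del = 1, sub = 1))[1, ]
      dmin <- min(dists)
      if (dmin > max_distance) { unmatched <- c(unmatched, kw); next }
      cand <- which(dists == dmin)
      i <- cand[order(mm$mention[cand], mm$entity_id[cand])][1]
      d <- as.integer(dmin)
    }
    hits[[length(hits) + 1L]] <- data.frame(
      keyword = kw, mention = mm$mention[i], entity_id = mm$entity_id[i],
      entity_type = mm$entity_type[i], distance = d, stringsAsFactors = FALSE)
  }
  matched <- if (length(hits) > 0) do.call(rbind, hits)
             else data.frame(keyword = character(0), mention = character(0),
                             entity_id = integer(0), entity_type = character(0),
                             distance = integer(0), stringsAsFactors = FALSE)
  if (nrow(matched) > 0) {
    matched <- matched[order(matched$distance), , drop = FALSE]
    matched <- matched[!duplicated(matched$entity_id), , drop = FALSE]
    matched <- matched[order(matched$entity_id), , drop = FALSE]
    rownames(matched) <- NULL
  }
  structure(list(matched = matched, unmatched = unmatched),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat("match set:", nrow(x$matched), "matched entities,",
      length(x$unmatched), "unmatched keywords\n")
  if (nrow(x$matched) > 0) print(x$matched)
  invisible(x)
}
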