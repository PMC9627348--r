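# Ranked-retrieval evaluation: precision/recall/F1 at K, (mean) average
# precision, ground-truth pruning, and the benchmark harness comparing
# rankers over a K grid.

DEFAULT_K_GRID <- c(1L, 2L, 5L, 10L, 25L, 50L, 75L, 100L, 150L, 250L, 500L, 1000L)

#' Precision, recall and F1 at a cutoff
#'
#' With R the number of relevant articles among the top-K retrieved:
#' precision = R / |top-K retrieved|, recall = R / |relevant|,
#' F1 = 2PR / (P + R) (0 when P + R = 0).
#'
#' @param retrieved ordered vector of retrieved pmids.
#' @param relevant vector (treated as a set) of relevant pmids; must be
#'   nonempty.
#' @param k cutoff.
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(retrieved, relevant, k) {
  stopifnot(k >= 1)
  relevant <- unique(relevant)
  if (length(relevant) == 0)
    stop_with("kgsearch_invalid_input", "relevant set is empty")
  top <- utils::head(retrieved, k)
  r <- length(intersect(top, relevant))
  p <- if (length(top) == 0) 0 else r / length(top)
  rec <- r / length(relevant)
  f1 <- if (p + rec == 0) 0 else 2 * p * rec / (p + rec)
  c(precision = p, recall = rec, f1 = f1)
}

#' Average precision of a ranked list
#'
#' Two variants: `"standard"` averages precision at the ranks of relevant
#' retrieved items, divided by min(|relevant|, K); `"all-positions"` averages
#' precision at every rank up to K regardless of relevance.
#'
#' @inheritParams precision_recall_f1
#' @param variant `"standard"` (default) or `"all-positions"`.
#' @return scalar in \[0, 1\].
#' @export
average_precision <- function(retrieved, relevant, k,
                              variant = c("standard", "all-positions")) {
  variant <- match.arg(variant)
  stopifnot(k >= 1)
  relevant <- unique(relevant)
  if (length(relevant) == 0)
    stop_with("kgsearch_invalid_input", "relevant set is empty")
  top <- utils::head(retrieved, k)
  if (length(top) == 0) return(0)
  hits <- top %in% relevant
  prec_at <- cumsum(hits) / seq_along(top)
  if (variant == "standard") {
    if (!any(hits)) return(0)
    sum(prec_at[hits]) / min(length(relevant), k)
  } else {
    mean(prec_at)
  }
}

#' Mean average precision across queries
#'
#' @param results named list: query id -> ordered retrieved pmid vector.
#' @param judgments named list: query id -> relevant pmid vector (ordered as
#'   given by the ground-truth source).
#' @param k cutoff.
#' @param variant passed to [average_precision()].
#' @return scalar MAP.
#' @export
mean_average_precision <- function(results, judgments, k,
                                   variant = c("standard", "all-positions")) {
  variant <- match.arg(variant)
  missing <- setdiff(names(results), names(judgments))
  if (length(missing) > 0)
    stop_with("kgsearch_missing_judgment",
              paste("no judgment for query:", paste(missing, collapse = ", ")))
  ap <- vapply(names(results), function(qid)
    average_precision(results[[qid]], judgments[[qid]], k, variant), 1)
  mean(ap)
}

#' Prune judgments to their top-K ground-truth entries
#'
#' Truncates each relevant list (kept in ground-truth order) to its first `k`
#' entries.
#' @param judgments named list of ordered relevant pmid vectors.
#' @param k cutoff.
#' @return judgments of the same shape.
#' @export
prune_judgments <- function(judgments, k) {
  stopifnot(k >= 1)
  lapply(judgments, function(x) utils::head(x, k))
}

#' Benchmark rankers over a K grid
#'
#' Runs each ranker once per query (retrieving the full list), then scores
#' precision, recall, F1 and MAP at every K, averaged over queries. A ranker
#' failure or empty output scores 0 on that query and the run continues.
#'
#' @param methods named list of ranker functions `f(query_text) ->` ordered
#'   integer pmid vector.
#' @param queries data.frame with `query_id` and `text` columns (e.g. a
#'   `query_set`).
#' @param judgments named list: query id -> ordered relevant pmids.
#' @param k_grid integer cutoffs (default the 12-level grid
#'   1,2,5,10,25,50,75,100,150,250,500,1000).
#' @param prune when `TRUE`, judgments are pruned to their top K before
#'   scoring at each K.
#' @param map_variant passed to [average_precision()].
#' @return an `eval_report`: list with `metrics` (long data.frame method, k,
#'   metric, value), `per_query` (data.frame), `failures` (character).
#' @export
run_benchmark <- function(methods, queries, judgments,
                          k_grid = DEFAULT_K_GRID, prune = FALSE,
                          map_variant = "standard") {
  stopifnot(is.list(methods), !is.null(names(methods)))
  missing <- setdiff(queries$query_id, names(judgments))
  if (length(missing) > 0)
    stop_with("kgsearch_missing_judgment",
              paste("no judgment for query:", paste(missing, collapse = ", ")))
  failures <- character(0)
  retrieved <- list()
  for (m in names(methods)) {
    retrieved[[m]] <- lapply(seq_len(nrow(queries)), function(i) {
      out <- tryCatch(methods[[m]](queries$text[i]), error = function(e) {
        failures <<- c(failures, sprintf("%s / %s: %s", m, queries$query_id[i],
                                         conditionMessage(e)))
        integer(0)
      })
      as.integer(out)
    })
    names(retrieved[[m]]) <- queries$query_id
  }
  rows <- list()
  per_query <- list()
  for (m in names(methods)) {
    for (k in k_grid) {
      jk <- if (prune) prune_judgments(judgments, k) else judgments
      pq <- t(vapply(queries$query_id, function(qid) {
        ret <- retrieved[[m]][[qid]]
        rel <- jk[[qid]]
        if (length(rel) == 0 || length(ret) == 0) {
          c(precision = 0, recall = 0, f1 = 0, ap = 0)
        } else {
          c(precision_recall_f1(ret, rel, k),
            ap = average_precision(ret, rel, k, map_variant))
        }
      }, c(precision = 0, recall = 0, f1 = 0, ap = 0)))
      per_query[[length(per_query) + 1L]] <-
        data.frame(method = m, k = k, query_id = queries$query_id,
                   precision = pq[, "precision"], recall = pq[, "recall"],
                   f1 = pq[, "f1"], ap = pq[, "ap"], row.names = NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, k = k,
        metric = c("recall", "precision", "f1", "map"),
        value = c(mean(pq[, "recall"]), mean(pq[, "precision"]),
                  mean(pq[, "f1"]), mean(pq[, "ap"])))
    }
  }
  structure(list(metrics = do.call(rbind, rows),
                 per_query = do.call(rbind, per_query),
                 failures = failures, k_grid = k_grid, prune = prune),
            class = "eval_report")
}

#' Wide metric-by-method-by-K table from a benchmark report
#'
#' One row per (metric, method), one column per K.
#' @param report an `eval_report`.
#' @return data.frame.
#' @export
report_table <- function(report) {
  m <- report$metrics
  wide <- stats::reshape(m, idvar = c("metric", "method"), timevar = "k",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "K=", names(wide))
  ord <- order(match(wide$metric, c("recall", "precision", "f1", "map")),
               wide$method)
  wide <- wide[ord, ]
  rownames(wide) <- NULL
  wide
}

#' @export
print.eval_report <- function(x, ...) {
  cat("retrieval benchmark over", length(unique(x$metrics$method)),
      "methods,", length(unique(x$per_query$query_id)), "queries,",
      length(x$k_grid), "K levels\n")
  print(report_table(x), digits = 3)
  if (length(x$failures) > 0)
    cat("failures:", paste(x$failures, collapse = "; "), "\n")
  invisible(x)
}

#' Write / read a judgments file
#'
#' TSV with columns query_id, text, relevant (comma-separated pmids in
#' ground-truth order).
#' @param queries a `query_set` (or data.frame query_id, text with a
#'   `relevant` attribute or list).
#' @param judgments named list of relevant pmid vectors (defaults to the
#'   `relevant` attribute of `queries`).
#' @param path file path.
#' @return `path` invisibly for the writer; for the reader, a list with
#'   `queries` (data.frame) and `judgments` (named list).
#' @export
write_judgments <- function(queries, path, judgments = attr(queries, "relevant")) {
  df <- data.frame(query_id = queries$query_id, text = queries$text,
                   relevant = vapply(judgments[queries$query_id],
                                     function(x) paste(x, collapse = ","), ""),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_judgments
#' @export
read_judgments <- function(path) {
  if (!file.exists(path))
    stop_with("kgsearch_missing_artifact", paste("missing judgments file:", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE)
  judgments <- lapply(strsplit(df$relevant, ",", fixed = TRUE), as.integer)
  names(judgments) <- df$query_id
  list(queries = df[, c("query_id", "text")], judgments = judgments)
}
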