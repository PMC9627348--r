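# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so library code never clobbers
#' the session stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Normalize a mention string for index keys and matching
#'
#' Case-fold, strip punctuation, collapse runs of whitespace.
#' @param x character vector.
#' @return character vector of the same length.
#' @export
normalize_mention <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Derive a per-stage seed from the pipeline master seed; kept within 32-bit
# integer range.
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L) + 1L
}

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= min && x == as.integer(x)
}

is_count_range <- function(x, min = 0) {
  length(x) == 2 && is.numeric(x) && !anyNA(x) &&
    all(x == as.integer(x)) && x[1] >= min && x[2] >= x[1]
}

stop_with <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "kgsearch_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
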