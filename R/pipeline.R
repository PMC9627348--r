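# End-to-end pipeline and state persistence: simulate -> build KG -> embed ->
# pool -> index -> (optionally) evaluate. All artifacts are plain text so a
# state directory round-trips losslessly.

#' Pipeline configuration
#'
#' A single validated container for every stage's parameters. All randomness
#' flows from `seed` through per-stage substreams.
#'
#' @param synth a [synth_config()] describing the corpus to simulate (ignored
#'   when prebuilt tables are supplied to [run_pipeline()]).
#' @param embedding an [embedding_config()].
#' @param windows sliding-window sizes for query expansion.
#' @param max_distance Levenshtein threshold for entity matching.
#' @param k_grid evaluation cutoffs.
#' @param prune prune judgments to their top K before scoring.
#' @param n_queries number of planted evaluation queries.
#' @param map_variant average-precision variant (see [average_precision()]).
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(), embedding = embedding_config(),
                            windows = c(2L, 3L, 4L), max_distance = 1L,
                            k_grid = DEFAULT_K_GRID, prune = FALSE,
                            n_queries = 15L, map_variant = "standard",
                            seed = 1L) {
  if (!all(k_grid == as.integer(k_grid)) || any(k_grid < 1))
    stop_with("kgsearch_invalid_config", "k_grid must be positive integers")
  if (!max_distance >= 0)
    stop_with("kgsearch_invalid_config", "max_distance must be >= 0")
  seed <- as.integer(seed)
  synth$seed <- stage_seed(seed, 1L)
  embedding$seed <- stage_seed(seed, 2L)
  structure(list(synth = synth, embedding = embedding, windows = windows,
                 max_distance = max_distance, k_grid = as.integer(k_grid),
                 prune = isTRUE(prune), n_queries = as.integer(n_queries),
                 map_variant = map_variant, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected. Nested `synth` and `embedding` blocks map to
#' [synth_config()] and [embedding_config()] arguments.
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  top <- c("synth", "embedding", "windows", "max_distance", "k_grid", "prune",
           "n_queries", "map_variant", "seed")
  unknown <- setdiff(names(y), top)
  if (length(unknown) > 0)
    stop_with("kgsearch_invalid_config",
              paste("unknown config keys:", paste(unknown, collapse = ", ")))
  check_sub <- function(block, fn) {
    if (is.null(block)) return(list())
    unknown <- setdiff(names(block), names(formals(fn)))
    if (length(unknown) > 0)
      stop_with("kgsearch_invalid_config",
                paste("unknown config keys:", paste(unknown, collapse = ", ")))
    block
  }
  args <- y[setdiff(intersect(names(y), top), c("synth", "embedding"))]
  args$synth <- do.call(synth_config, check_sub(y$synth, synth_config))
  args$embedding <- do.call(embedding_config, check_sub(y$embedding, embedding_config))
  do.call(pipeline_config, args)
}

#' Persist a built system state to a directory
#'
#' Writes the knowledge graph (node/edge lists), node vectors and stage-2
#' article vectors (word2vec text), the entity index (TSV) and a metadata
#' JSON recording dimensions and targets.
#'
#' @param state list with `graph`, `index`, `emb`, `art_vecs`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
save_state <- function(state, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_kg(state$graph, dir)
  write_word2vec(state$emb, file.path(dir, "vectors.w2v"))
  write_word2vec(state$art_vecs$stage1, file.path(dir, "articles.stage1.w2v"))
  write_word2vec(state$art_vecs$stage2, file.path(dir, "articles.stage2.w2v"))
  utils::write.table(state$index$mentions, file.path(dir, "index.mentions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  arts <- data.frame(entity_id = rep(names(state$index$articles),
                                     lengths(state$index$articles)),
                     pmid = unlist(state$index$articles, use.names = FALSE))
  utils::write.table(arts, file.path(dir, "index.articles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(dim = ncol(state$emb), targets = state$art_vecs$targets)
  jsonlite::write_json(meta, file.path(dir, "state.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load and cross-validate a persisted system state
#'
#' Fails with distinct condition classes: `kgsearch_missing_artifact` when a
#' file is absent, `kgsearch_dim_mismatch` when vector dimensions disagree,
#' `kgsearch_vocab_mismatch` when article vectors name pmids missing from the
#' knowledge graph.
#'
#' @param dir directory written by [save_state()].
#' @return state list (`graph`, `index`, `emb`, `art_vecs`).
#' @export
load_state <- function(dir) {
  for (f in c("kg.nodes.tsv", "kg.edges.tsv", "vectors.w2v",
              "articles.stage1.w2v", "articles.stage2.w2v",
              "index.mentions.tsv", "index.articles.tsv", "state.json")) {
    if (!file.exists(file.path(dir, f)))
      stop_with("kgsearch_missing_artifact", paste("missing state artifact:", f))
  }
  graph <- read_kg(dir)
  emb <- read_word2vec(file.path(dir, "vectors.w2v"))
  s1 <- read_word2vec(file.path(dir, "articles.stage1.w2v"))
  s2 <- read_word2vec(file.path(dir, "articles.stage2.w2v"))
  meta <- jsonlite::read_json(file.path(dir, "state.json"), simplifyVector = TRUE)
  dims <- c(ncol(emb), ncol(s1), ncol(s2), meta$dim)
  if (length(unique(dims)) != 1)
    stop_with("kgsearch_dim_mismatch",
              paste("vector dimensions disagree:", paste(dims, collapse = " / ")))
  v_names <- igraph::V(graph)$name
  if (!all(rownames(emb) %in% v_names) || !all(rownames(s2) %in% v_names))
    stop_with("kgsearch_vocab_mismatch",
              "vector vocabularies name nodes absent from the knowledge graph")
  mm <- utils::read.table(file.path(dir, "index.mentions.tsv"), sep = "\t",
                          header = TRUE, quote = "", stringsAsFactors = FALSE)
  arts <- utils::read.table(file.path(dir, "index.articles.tsv"), sep = "\t",
                            header = TRUE, quote = "", stringsAsFactors = FALSE)
  index <- structure(
    list(mentions = mm,
         articles = lapply(split(arts$pmid, arts$entity_id), sort)),
    class = "entity_index")
  art_vecs <- structure(list(stage1 = s1, stage2 = s2,
                             targets = sort(as.integer(meta$targets)),
                             dim = ncol(s2)),
                        class = "article_vectors")
  list(graph = graph, index = index, emb = emb, art_vecs = art_vecs)
}

#' Run the full pipeline
#'
#' simulate (unless `tables` is given) -> build triples and graph -> embed
#' nodes -> pool article vectors -> build entity index -> plant evaluation
#' queries -> benchmark the embedding ranker against the TF-IDF baseline.
#' Each stage appends input/output sizes and wall time to the returned log.
#'
#' @param config a [pipeline_config()].
#' @param tables optional prebuilt metadata tables (skips simulation).
#' @param out_dir optional directory: persists state, judgments and the
#'   report (TSV + JSON).
#' @param evaluate run the benchmark stage (default `TRUE`).
#' @return list with `tables`, `graph`, `index`, `emb`, `art_vecs`,
#'   `queries`, `judgments`, `report`, `summary`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), tables = NULL,
                         out_dir = NULL, evaluate = TRUE) {
  log <- list()
  tick <- function(stage, sizes) {
    log[[stage]] <<- c(list(time = format(Sys.time(), "%H:%M:%OS2")), sizes)
  }
  if (is.null(tables)) {
    t0 <- proc.time()[3]
    tables <- generate_tables(config$synth)
    tick("simulate", list(articles = nrow(tables$articles),
                          mentions = nrow(tables$mentions),
                          seconds = round(proc.time()[3] - t0, 2)))
  }
  t0 <- proc.time()[3]
  triples <- build_triples(tables)
  graph <- assemble_graph(triples)
  tick("build_kg", list(triples = nrow(triples), nodes = igraph::vcount(graph),
                        edges = igraph::ecount(graph),
                        seconds = round(proc.time()[3] - t0, 2)))

  t0 <- proc.time()[3]
  corpus <- sample_walks(graph, config$embedding)
  emb <- train_skipgram(corpus, config$embedding)
  tick("embed", list(walks = length(corpus$walks), tokens = corpus$n_tokens,
                     dim = ncol(emb), seconds = round(proc.time()[3] - t0, 2)))

  t0 <- proc.time()[3]
  art_vecs <- article_embeddings(graph, emb)
  index <- build_entity_index(tables$mentions)
  tick("pool_index", list(articles = nrow(art_vecs$stage2),
                          mentions = nrow(index$mentions),
                          seconds = round(proc.time()[3] - t0, 2)))

  state <- list(graph = graph, index = index, emb = emb, art_vecs = art_vecs)
  out <- c(list(tables = tables), state, list(log = log))
  out$summary <- kg_summary(graph)

  if (evaluate) {
    t0 <- proc.time()[3]
    queries <- generate_query_set(tables, config$n_queries,
                                  seed = stage_seed(config$seed, 3L))
    judgments <- attr(queries, "relevant")
    n_all <- length(art_vecs$targets)
    methods <- list(
      kg_embedding = function(text) {
        res <- kg_search(text, state, k = n_all, windows = config$windows,
                         max_distance = config$max_distance)
        if (inherits(res, "search_no_match")) integer(0) else res$pmid
      },
      tfidf = local({
        model <- fit_tfidf(tables$articles)
        function(text) tfidf_rank(text, model, k = n_all)$pmid
      })
    )
    report <- run_benchmark(methods, queries, judgments,
                            k_grid = config$k_grid, prune = config$prune,
                            map_variant = config$map_variant)
    log[["evaluate"]] <- list(queries = nrow(queries),
                              seconds = round(proc.time()[3] - t0, 2))
    out$queries <- queries
    out$judgments <- judgments
    out$report <- report
    out$log <- log
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    save_state(state, out_dir)
    write_tables(tables, file.path(out_dir, "tables"))
    if (evaluate) {
      write_judgments(out$queries, file.path(out_dir, "judgments.tsv"))
      utils::write.table(report_table(out$report),
                         file.path(out_dir, "report.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(out$report$metrics, file.path(out_dir, "report.json"),
                           dataframe = "rows", digits = NA)
    }
  }
  out
}
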