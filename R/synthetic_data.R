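#' Configuration for the synthetic metadata generator
#'
#' Describes a PubMed-like corpus with planted topical structure: articles are
#' assigned to topics, bio-entities (drugs, diseases, genes, species) live in
#' per-topic pools, articles mention mostly entities from their own topic, and
#' citations prefer earlier articles of the same topic. The defaults define the
#' reference study corpus used throughout the package's tests and examples:
#' 200 articles in 4 topics with a strong (0.9) intra-topic citation bias.
#'
#' @param n_articles number of articles.
#' @param n_topics number of planted topics.
#' @param entities_per_topic entities per topic for each of the four bio-entity
#'   types (drug, disease, gene, species).
#' @param mentions_per_article integer range `c(lo, hi)`: entity mentions drawn
#'   per article.
#' @param n_authors size of the author pool.
#' @param n_projects size of the NIH-project pool (0 disables the table).
#' @param n_mesh size of the MeSH-heading pool (0 disables the table).
#' @param citation_intra_topic_prob probability that a citation stays within
#'   the citing article's topic.
#' @param citations_per_article integer range `c(lo, hi)`: references emitted
#'   per article (capped by the number of earlier articles).
#' @param mention_variant_count surface strings per entity; variant 1 is the
#'   base name, variant 2 changes case, further variants append a character so
#'   fuzzy matching at edit distance 1 is exercised.
#' @param seed integer seed; identical seeds give identical tables.
#' @return a `synth_config` list, validated.
#' @export
synth_config <- function(n_articles = 200, n_topics = 4, entities_per_topic = 3,
                         mentions_per_article = c(2L, 5L), n_authors = 100,
                         n_projects = 20, n_mesh = 30,
                         citation_intra_topic_prob = 0.9,
                         citations_per_article = c(2L, 6L),
                         mention_variant_count = 3, seed = 1L) {
  cfg <- list(
    n_articles = n_articles, n_topics = n_topics,
    entities_per_topic = entities_per_topic,
    mentions_per_article = mentions_per_article, n_authors = n_authors,
    n_projects = n_projects, n_mesh = n_mesh,
    citation_intra_topic_prob = citation_intra_topic_prob,
    citations_per_article = citations_per_article,
    mention_variant_count = mention_variant_count, seed = as.integer(seed)
  )
  for (f in c("n_articles", "n_topics", "entities_per_topic", "n_authors",
              "mention_variant_count")) {
    if (!is_count(cfg[[f]]))
      stop_with("kgsearch_invalid_config", sprintf("'%s' must be a count >= 1", f))
  }
  for (f in c("n_projects", "n_mesh")) {
    if (!is_count(cfg[[f]], min = 0))
      stop_with("kgsearch_invalid_config", sprintf("'%s' must be a count >= 0", f))
  }
  for (f in c("mentions_per_article", "citations_per_article")) {
    if (!is_count_range(cfg[[f]]))
      stop_with("kgsearch_invalid_config", sprintf("'%s' must be an integer range c(lo, hi)", f))
  }
  p <- cfg$citation_intra_topic_prob
  if (!(length(p) == 1 && is.numeric(p) && !is.na(p) && p >= 0 && p <= 1))
    stop_with("kgsearch_invalid_config", "'citation_intra_topic_prob' must lie in [0, 1]")
  if (cfg$citations_per_article[2] > cfg$n_articles - 1)
    stop_with("kgsearch_invalid_config",
              "citations_per_article upper bound exceeds n_articles - 1")
  if (cfg$mentions_per_article[1] < 1)
    stop_with("kgsearch_invalid_config", "mentions_per_article lower bound must be >= 1")
  class(cfg) <- "synth_config"
  cfg
}

# Deterministic pronounceable entity names, disjoint from the filler
# vocabulary (fillers carry digits, names never do). Roughly a third of the
# names are two-token so sliding-window query expansion has real work to do.
make_entity_names <- function(n) {
  syl <- c("al", "ber", "cor", "dex", "fen", "gli", "hep", "ixa", "lor", "mab",
           "nex", "oro", "pra", "quin", "rax", "sol", "tam", "umab", "vir", "zol")
  one <- function(i) {
    i <- i - 1L
    a <- syl[i %% 20L + 1L]
    b <- syl[(i %/% 20L) %% 20L + 1L]
    c <- syl[(i %/% 400L) %% 20L + 1L]
    paste0(a, b, c)
  }
  base <- vapply(seq_len(n), one, "")
  two_tok <- seq_len(n) %% 3L == 0L
  base[two_tok] <- paste(base[two_tok],
                         c("acid", "syndrome", "factor", "strain")[(seq_len(n) %% 4L + 1L)[two_tok]])
  base
}

# Surface variant v of a base name: 1 = base, 2 = capitalised base
# (normalisation-equivalent), >2 = base plus one appended character
# (edit distance 1 from the base).
mention_variant <- function(base, v) {
  suffix <- letters[pmin(pmax(v - 2L, 1L), 26L)]
  ifelse(v == 1L, base,
         ifelse(v == 2L,
                paste0(toupper(substr(base, 1, 1)), substr(base, 2, nchar(base))),
                paste0(base, suffix)))
}

#' Generate synthetic PubMed-like metadata tables
#'
#' Produces the relational tables a literature knowledge graph is built from:
#' articles (with token streams for a bag-of-words baseline), author lists,
#' bio-entity mentions, a citation list, NIH-project links, MeSH assignments,
#' and the derived ground truth (an article is relevant to an entity iff it
#' mentions it). Articles are assigned to topics in balanced fashion; each
#' article mentions entities drawn mostly from its own topic's pool; citations
#' point to earlier articles, within-topic with probability
#' `citation_intra_topic_prob`.
#'
#' @param config a [synth_config()].
#' @return a `synth_tables` list with data.frame components `articles`,
#'   `authors`, `mentions`, `references`, `projects`, `mesh`, `truth`, and an
#'   `entities` catalog (entity_id, entity_type, topic, base name).
#' @export
generate_tables <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  with_seed(config$seed, generate_tables_impl(config))
}

generate_tables_impl <- function(cfg) {
  n <- cfg$n_articles
  types <- c("drug", "disease", "gene", "species")

  # balanced topic assignment, randomly permuted
  topic <- sample(rep_len(seq_len(cfg$n_topics), n))
  pmid <- seq_len(n)

  # entity catalog: entities_per_topic per (type, topic)
  ent <- expand.grid(slot = seq_len(cfg$entities_per_topic),
                     entity_type = types, topic = seq_len(cfg$n_topics),
                     stringsAsFactors = FALSE)
  ent$entity_id <- seq_len(nrow(ent))
  ent$name <- make_entity_names(nrow(ent))
  entities <- ent[, c("entity_id", "entity_type", "topic", "name")]

  # mentions: mostly from the article's own topic pool
  m_lo <- cfg$mentions_per_article[1]; m_hi <- cfg$mentions_per_article[2]
  n_m <- sample(m_lo:m_hi, n, replace = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    own <- entities$entity_id[entities$topic == topic[i]]
    other <- entities$entity_id[entities$topic != topic[i]]
    pick <- integer(n_m[i])
    for (j in seq_len(n_m[i])) {
      pool <- if (length(other) == 0 || stats::runif(1) < 0.85) own else other
      pick[j] <- pool[sample.int(length(pool), 1)]
    }
    pick <- unique(pick)
    v <- sample.int(cfg$mention_variant_count, length(pick), replace = TRUE)
    rows[[i]] <- data.frame(
      pmid = pmid[i], entity_id = pick,
      entity_type = entities$entity_type[pick],
      mention = mention_variant(entities$name[pick], v),
      stringsAsFactors = FALSE
    )
  }
  mentions <- do.call(rbind, rows)

  # abstracts: filler vocabulary (digit-bearing, disjoint from entity names)
  # interleaved with the article's own mention strings
  filler <- sprintf("w%03d", seq_len(150))
  abs_tok <- vapply(seq_len(n), function(i) {
    f <- sample(filler, 25, replace = TRUE)
    m <- mentions$mention[mentions$pmid == pmid[i]]
    paste(sample(c(f, m)), collapse = " ")
  }, "")
  title_tok <- vapply(seq_len(n), function(i) {
    m <- mentions$mention[mentions$pmid == pmid[i]]
    paste(c(sample(filler, 3, replace = TRUE), m[1]), collapse = " ")
  }, "")
  articles <- data.frame(pmid = pmid, title = title_tok, abstract = abs_tok,
                         topic = topic, stringsAsFactors = FALSE)

  # authors: 1-4 per article from a shared pool
  n_a <- sample(1:4, n, replace = TRUE)
  authors <- data.frame(
    pmid = rep(pmid, n_a),
    aid = unlist(lapply(n_a, function(k) sample.int(cfg$n_authors, k))),
    stringsAsFactors = FALSE
  )
  authors$name <- sprintf("author_%04d", authors$aid)

  # citations: to earlier-indexed articles, intra-topic with the configured
  # probability (when an earlier same/other-topic article exists)
  c_lo <- cfg$citations_per_article[1]; c_hi <- cfg$citations_per_article[2]
  ref_rows <- vector("list", n)
  for (i in seq_len(n)) {
    earlier <- pmid[seq_len(i - 1L)]
    if (length(earlier) == 0) next
    k <- min(sample(c_lo:c_hi, 1), length(earlier))
    same <- earlier[topic[earlier] == topic[i]]
    diff <- earlier[topic[earlier] != topic[i]]
    cited <- integer(0)
    for (j in seq_len(k)) {
      # draw the intra/inter side first; skip the citation when that side has
      # no remaining candidate, so every emitted edge is intra-topic with
      # exactly the configured probability
      intra <- stats::runif(1) < cfg$citation_intra_topic_prob
      pool <- if (intra) setdiff(same, cited) else setdiff(diff, cited)
      if (length(pool) == 0) next
      cited <- c(cited, pool[sample.int(length(pool), 1)])
    }
    if (length(cited) > 0)
      ref_rows[[i]] <- data.frame(pmid = pmid[i], cited_pmid = cited,
                                  stringsAsFactors = FALSE)
  }
  references <- do.call(rbind, ref_rows)
  if (is.null(references))
    references <- data.frame(pmid = integer(0), cited_pmid = integer(0))

  # funding: ~30% of articles carry one NIH project
  projects <- data.frame(pmid = integer(0), project_id = integer(0))
  if (cfg$n_projects > 0) {
    has <- stats::runif(n) < 0.3
    if (any(has))
      projects <- data.frame(pmid = pmid[has],
                             project_id = sample.int(cfg$n_projects, sum(has),
                                                     replace = TRUE))
  }

  # MeSH: 1-3 headings per article
  mesh <- data.frame(pmid = integer(0), header_id = integer(0))
  if (cfg$n_mesh > 0) {
    n_h <- sample(1:3, n, replace = TRUE)
    mesh <- data.frame(
      pmid = rep(pmid, n_h),
      header_id = unlist(lapply(n_h, function(k)
        sample.int(cfg$n_mesh, min(k, cfg$n_mesh))))
    )
  }

  truth <- unique(mentions[, c("entity_id", "pmid")])
  truth <- truth[order(truth$entity_id, truth$pmid), ]
  rownames(truth) <- NULL

  structure(list(articles = articles, authors = authors, mentions = mentions,
                 references = references, projects = projects, mesh = mesh,
                 truth = truth, entities = entities, config = cfg),
            class = "synth_tables")
}

#' @export
print.synth_tables <- function(x, ...) {
  cat("synthetic metadata tables:",
      nrow(x$articles), "articles,",
      length(unique(x$articles$topic)), "topics,",
      nrow(x$mentions), "mentions of", nrow(x$entities), "entities,",
      nrow(x$references), "citation rows\n")
  invisible(x)
}

#' Sample evaluation queries with planted ground truth
#'
#' Each query is a surface mention string of one sampled entity; its relevant
#' set is the ground-truth article list for that entity (the articles that
#' mention it). Entities with an empty relevant set are never emitted.
#'
#' @param tables a `synth_tables` object.
#' @param n_queries number of distinct entity queries.
#' @param seed integer seed.
#' @return a `query_set`: data.frame (query_id, text, entity_id) with a
#'   `relevant` attribute, a list of integer pmid vectors named by query_id.
#' @export
generate_query_set <- function(tables, n_queries, seed = 1L) {
  stopifnot(inherits(tables, "synth_tables"))
  if (nrow(tables$articles) == 0)
    stop_with("kgsearch_invalid_input", "tables are empty")
  eligible <- unique(tables$truth$entity_id)
  if (n_queries > length(eligible))
    stop_with("kgsearch_invalid_input",
              sprintf("n_queries (%d) exceeds the %d distinct entities with truth",
                      n_queries, length(eligible)))
  with_seed(seed, {
    ids <- sort(sample(eligible, n_queries))
    text <- vapply(ids, function(e) {
      vars <- sort(unique(tables$mentions$mention[tables$mentions$entity_id == e]))
      vars[sample.int(length(vars), 1)]
    }, "")
    relevant <- lapply(ids, function(e)
      sort(tables$truth$pmid[tables$truth$entity_id == e]))
    qs <- data.frame(query_id = sprintf("q%02d", seq_along(ids)), text = text,
                     entity_id = ids, stringsAsFactors = FALSE)
    names(relevant) <- qs$query_id
    attr(qs, "relevant") <- relevant
    class(qs) <- c("query_set", "data.frame")
    qs
  })
}

# table name <-> file name for on-disk layout
synth_table_files <- c(
  articles = "A01_Articles.tsv", authors = "A02_AuthorList.tsv",
  mentions = "B10_BERN_Main.tsv", references = "C04_ReferenceList.tsv",
  projects = "C05_NIH_PubMed.tsv", mesh = "mesh.tsv", truth = "truth.tsv"
)

#' Write metadata tables as TSV files
#'
#' @param tables a `synth_tables` object (or compatible list of data.frames).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(synth_table_files)) {
    utils::write.table(tables[[nm]], file.path(dir, synth_table_files[[nm]]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read metadata tables from a directory of TSV files
#'
#' @param dir directory produced by [write_tables()].
#' @return a `synth_tables` object (without the generator config).
#' @export
read_tables <- function(dir) {
  out <- lapply(synth_table_files, function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path))
      stop_with("kgsearch_missing_artifact", paste("missing table file:", path))
    utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                      stringsAsFactors = FALSE)
  })
  names(out) <- names(synth_table_files)
  structure(out, class = "synth_tables")
}
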