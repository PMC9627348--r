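# Typed knowledge-graph construction from relational metadata tables.
#
# Node identity convention: "<type>/<id-namespace>/<raw-id>", e.g.
# "article/pmid/652148", "author/aid/6754", "bioentity/drug/1256".
# The graph is undirected; each bidirectional relation name is stored as one
# labeled edge.

BIOENTITY_TYPES <- c("drug", "disease", "gene", "species")

NODE_NAMESPACES <- c(
  article = "article/pmid", author = "author/aid",
  drug = "bioentity/drug", disease = "bioentity/disease",
  gene = "bioentity/gene", species = "bioentity/species",
  nih_project = "nih_project/project_id", mesh_term = "mesh_term/header_id",
  substance = "substance/substance_id"
)

EDGE_LABELS <- c(
  "article-writtenBy-author",
  "article-mentions-disease", "article-mentions-drug",
  "article-mentions-gene", "article-mentions-species",
  "article-cites-article", "article-isFundedBy-NIHProject",
  "article-relatedTo-MeSHTerm", "article-relatedTo-substances"
)

#' Canonical prefixed node identifier
#'
#' @param node_type one of `"article"`, `"author"`, `"drug"`, `"disease"`,
#'   `"gene"`, `"species"`, `"nih_project"`, `"mesh_term"`, `"substance"`.
#' @param raw_id the bare identifier from the source table (no slashes).
#' @return character vector of node ids like `"article/pmid/652148"`.
#' @export
make_node_id <- function(node_type, raw_id) {
  if (length(node_type) == 1) node_type <- rep(node_type, length(raw_id))
  bad <- !(node_type %in% names(NODE_NAMESPACES))
  if (any(bad))
    stop_with("kgsearch_unknown_type",
              paste("unknown node type:", paste(unique(node_type[bad]), collapse = ", ")))
  if (any(grepl("/", as.character(raw_id), fixed = TRUE)))
    stop_with("kgsearch_invalid_input",
              "raw_id must be a bare identifier (already-prefixed ids are rejected)")
  paste0(NODE_NAMESPACES[node_type], "/", raw_id)
}

#' Node type of a prefixed node id
#'
#' The type is a pure function of the id prefix; bio-entity ids carry their
#' entity type in the second path component.
#' @param node_id character vector of prefixed ids.
#' @return character vector of types.
#' @export
node_type_of <- function(node_id) {
  parts <- strsplit(node_id, "/", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 3)
      stop_with("kgsearch_invalid_input", paste("unparseable node id:", paste(p, collapse = "/")))
    if (p[1] == "bioentity") p[2] else p[1]
  }, "")
}

pmid_of <- function(node_id) {
  as.integer(sub("^article/pmid/", "", node_id))
}

#' Extract subject-predicate-object triples from metadata tables
#'
#' One triple per deduplicated metadata row: authorship, typed entity mention
#' (head = bio-entity, tail = article, as in the mention relation's natural
#' reading "is mentioned in"), citation, funding, MeSH assignment and, when a
#' `substances` table is present, chemical-substance assignment.
#'
#' @param tables a `synth_tables` object or a list with the same components.
#' @return data.frame (head, relation, tail); rows whose entity type is not
#'   recognised are skipped and reported in the `"row_errors"` attribute.
#' @export
build_triples <- function(tables) {
  trip <- list()
  errors <- character(0)
  add <- function(head, relation, tail) {
    if (length(head) > 0)
      trip[[length(trip) + 1L]] <<- data.frame(head = head, relation = relation,
                                               tail = tail, stringsAsFactors = FALSE)
  }
  if (!is.null(tables$authors) && nrow(tables$authors) > 0) {
    a <- unique(tables$authors[, c("pmid", "aid")])
    add(make_node_id("article", a$pmid), "article-writtenBy-author",
        make_node_id("author", a$aid))
  }
  if (!is.null(tables$mentions) && nrow(tables$mentions) > 0) {
    m <- unique(tables$mentions[, c("pmid", "entity_id", "entity_type")])
    ok <- m$entity_type %in% BIOENTITY_TYPES
    if (any(!ok))
      errors <- c(errors, sprintf("mentions row %d: unknown entity type '%s'",
                                  which(!ok), m$entity_type[!ok]))
    m <- m[ok, , drop = FALSE]
    if (nrow(m) > 0)
      add(make_node_id(m$entity_type, m$entity_id),
          paste0("article-mentions-", m$entity_type),
          make_node_id("article", m$pmid))
  }
  if (!is.null(tables$references) && nrow(tables$references) > 0) {
    r <- unique(tables$references[, c("pmid", "cited_pmid")])
    r <- r[r$pmid != r$cited_pmid, , drop = FALSE]
    add(make_node_id("article", r$pmid), "article-cites-article",
        make_node_id("article", r$cited_pmid))
  }
  if (!is.null(tables$projects) && nrow(tables$projects) > 0) {
    p <- unique(tables$projects[, c("pmid", "project_id")])
    add(make_node_id("article", p$pmid), "article-isFundedBy-NIHProject",
        make_node_id("nih_project", p$project_id))
  }
  if (!is.null(tables$mesh) && nrow(tables$mesh) > 0) {
    h <- unique(tables$mesh[, c("pmid", "header_id")])
    add(make_node_id("article", h$pmid), "article-relatedTo-MeSHTerm",
        make_node_id("mesh_term", h$header_id))
  }
  if (!is.null(tables$substances) && nrow(tables$substances) > 0) {
    s <- unique(tables$substances[, c("pmid", "substance_id")])
    add(make_node_id("article", s$pmid), "article-relatedTo-substances",
        make_node_id("substance", s$substance_id))
  }
  out <- if (length(trip) > 0) do.call(rbind, trip)
         else data.frame(head = character(0), relation = character(0),
                         tail = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "row_errors") <- errors
  out
}

#' Assemble the undirected typed knowledge graph from triples
#'
#' Nodes are the distinct heads and tails; duplicate triples and both
#' orientations of the same (endpoint pair, label) collapse to one undirected
#' labeled edge.
#'
#' @param triples data.frame from [build_triples()].
#' @return an [igraph::igraph] with vertex attributes `name`, `type` and edge
#'   attribute `label`.
#' @export
assemble_graph <- function(triples) {
  stopifnot(all(c("head", "relation", "tail") %in% names(triples)))
  bad <- !(triples$relation %in% EDGE_LABELS)
  if (any(bad))
    stop_with("kgsearch_invalid_input",
              paste("unknown edge label:", paste(unique(triples$relation[bad]), collapse = ", ")))
  nodes <- sort(unique(c(triples$head, triples$tail)))
  if (nrow(triples) > 0) {
    a <- pmin(triples$head, triples$tail)
    b <- pmax(triples$head, triples$tail)
    key <- paste(a, b, triples$relation, sep = "\r")
    keep <- !duplicated(key)
    edges <- data.frame(from = a[keep], to = b[keep],
                        label = triples$relation[keep], stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        label = character(0), stringsAsFactors = FALSE)
  }
  vdf <- data.frame(name = nodes, type = if (length(nodes)) node_type_of(nodes) else character(0),
                    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vdf)
}

#' Per-type node and per-label edge counts
#'
#' The shape of the usual KG summary table: total nodes, nodes per type, total
#' edges, edges per label.
#' @param graph a knowledge graph from [assemble_graph()].
#' @return list with `nodes` (named counts incl. `total`) and `edges` (same).
#' @export
kg_summary <- function(graph) {
  ntab <- table(igraph::V(graph)$type)
  etab <- if (igraph::ecount(graph) > 0) table(igraph::E(graph)$label) else table(character(0))
  list(
    nodes = c(total = igraph::vcount(graph),
              stats::setNames(as.integer(ntab), names(ntab))),
    edges = c(total = igraph::ecount(graph),
              stats::setNames(as.integer(etab), names(etab)))
  )
}

#' First-order citation closure of a seed set
#'
#' @param tables metadata tables containing a `references` data.frame.
#' @param seed_pmids integer vector of seed article ids.
#' @param order neighborhood order; only `1` is supported.
#' @return sorted integer vector: seeds plus every article citing or cited by
#'   a seed. Empty seed set gives an empty result.
#' @export
citation_closure <- function(tables, seed_pmids, order = 1) {
  if (order != 1)
    stop_with("kgsearch_invalid_input", "only first-order closure is supported")
  if (length(seed_pmids) == 0) return(integer(0))
  r <- tables$references
  hit <- r$pmid %in% seed_pmids | r$cited_pmid %in% seed_pmids
  sort(unique(as.integer(c(seed_pmids, r$pmid[hit], r$cited_pmid[hit]))))
}

#' Build the bio-entity index from the mentions table
#'
#' Maps normalized mention strings to entity ids and entity ids to the set of
#' articles mentioning them. Variant surface strings of one entity share its
#' identifier.
#'
#' @param mention_table data.frame (pmid, entity_id, entity_type, mention).
#' @return an `entity_index`: list with `mentions` (data.frame mention,
#'   entity_id, entity_type; unique, sorted) and `articles` (list entity_id ->
#'   sorted pmids). Rows with unrecognised entity types are skipped and
#'   reported in the `"row_errors"` attribute.
#' @export
build_entity_index <- function(mention_table) {
  req <- c("pmid", "entity_id", "entity_type", "mention")
  stopifnot(all(req %in% names(mention_table)))
  ok <- mention_table$entity_type %in% BIOENTITY_TYPES
  errors <- if (any(!ok))
    sprintf("mention row %d: unknown entity type '%s'",
            which(!ok), mention_table$entity_type[!ok]) else character(0)
  mt <- mention_table[ok, , drop = FALSE]
  mt$mention <- normalize_mention(mt$mention)
  mm <- unique(mt[, c("mention", "entity_id", "entity_type")])
  mm <- mm[order(mm$mention, mm$entity_id), ]
  rownames(mm) <- NULL
  arts <- lapply(split(mt$pmid, mt$entity_id), function(p) sort(unique(p)))
  idx <- structure(list(mentions = mm, articles = arts), class = "entity_index")
  attr(idx, "row_errors") <- errors
  idx
}

#' @export
print.entity_index <- function(x, ...) {
  cat("entity index:", nrow(x$mentions), "mention strings ->",
      length(x$articles), "entities\n")
  invisible(x)
}

#' Write a knowledge graph as plain-text node and edge lists
#'
#' @param graph knowledge graph.
#' @param dir output directory; writes `kg.nodes.tsv` (node_id, type),
#'   `kg.edges.tsv` (head, label, tail) and `kg.summary.json`.
#' @return `dir`, invisibly.
#' @export
write_kg <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- data.frame(node_id = igraph::V(graph)$name, type = igraph::V(graph)$type,
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(graph)
  edges <- data.frame(head = el[, 1],
                      label = if (nrow(el)) igraph::E(graph)$label else character(0),
                      tail = el[, 2], stringsAsFactors = FALSE)
  utils::write.table(nodes, file.path(dir, "kg.nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(edges, file.path(dir, "kg.edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(kg_summary(graph), file.path(dir, "kg.summary.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a knowledge graph written by [write_kg()]
#' @param dir directory holding `kg.nodes.tsv` and `kg.edges.tsv`.
#' @return an igraph knowledge graph.
#' @export
read_kg <- function(dir) {
  np <- file.path(dir, "kg.nodes.tsv"); ep <- file.path(dir, "kg.edges.tsv")
  if (!file.exists(np) || !file.exists(ep))
    stop_with("kgsearch_missing_artifact", "kg.nodes.tsv / kg.edges.tsv not found")
  nodes <- utils::read.table(np, sep = "\t", header = TRUE, quote = "",
                             stringsAsFactors = FALSE)
  edges <- utils::read.table(ep, sep = "\t", header = TRUE, quote = "",
                             stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    data.frame(from = edges$head, to = edges$tail, label = edges$label,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes$node_id, type = nodes$type,
                          stringsAsFactors = FALSE)
  )
}
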