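#' Recursive citation snowballing
#'
#' Breadth-first crawl over the citation graph: each frontier document is
#' ingested, its reference section segmented, each citation normalized into a
#' query, resolved against the backend, and the matched record's links
#' followed. Full texts retrieved at depth below `max_depth` join the next
#' frontier, so the crawl recursively pursues the references of what it has
#' already retrieved. A visited set keyed by [record_dedup_key()] guarantees
#' termination on any finite index, cycles included; seeds whose `doc_id`
#' names an index record are identified with that record, so re-discovering
#' a seed adds an edge, not a node.
#'
#' @param seeds List of `source_document` seeds (depth 0).
#' @param index A `bib_index` (used to resolve matched ids to records).
#' @param backend A `snowball_backend`; defaults to [local_backend()] over
#'   `index`.
#' @param fetcher Fetcher function (see [store_fetcher()]); `NULL` disables
#'   retrieval, so matched records become leaf nodes.
#' @param max_depth Maximum recursion depth; documents at depth
#'   `>= max_depth` are not expanded. Default 2.
#' @param k,tau,delta Matching parameters, see [search_candidates()] and
#'   [decide_match()].
#' @param min_len Query token length cutoff, see [build_query()].
#' @param heading_lexicon,footer_patterns Passed to
#'   [locate_reference_section()] and [segment_references()].
#' @return An object of class `citation_graph`: list with
#'   \describe{
#'     \item{nodes}{data.frame `id`, `kind` (`seed`/`record`), `depth`}
#'     \item{edges}{data.frame `citing`, `cited` (unique ordered pairs)}
#'     \item{unresolved}{data.frame `doc_id`, `index`, `status` for every
#'       citation that did not yield a match}
#'     \item{outcomes}{data.frame `record_id`, `outcome` for every fetched
#'       record}
#'     \item{decisions}{list of every `match_decision` made}
#'   }
#' @export
snowball <- function(seeds, index, backend = local_backend(index),
                     fetcher = NULL, max_depth = 2L, k = 5L, tau = 0.7,
                     delta = 0.05, min_len = 4L,
                     heading_lexicon = default_heading_lexicon(),
                     footer_patterns = default_footer_patterns()) {
  stopifnot(length(seeds) > 0L, max_depth >= 0L)
  if (inherits(seeds, "source_document")) seeds <- list(seeds)

  nodes <- list()
  edges <- new.env(parent = emptyenv())
  unresolved <- list()
  outcomes <- list()
  decisions <- list()
  visited <- new.env(parent = emptyenv())  # dedup key -> node id

  add_node <- function(id, kind, depth) {
    nodes[[length(nodes) + 1L]] <<- data.frame(id = id, kind = kind,
                                               depth = depth,
                                               stringsAsFactors = FALSE)
  }
  add_edge <- function(from, to) {
    edges[[paste(from, to, sep = "\t")]] <- TRUE
  }
  add_unresolved <- function(doc_id, index_, status) {
    unresolved[[length(unresolved) + 1L]] <<- data.frame(
      doc_id = doc_id, index = index_, status = status,
      stringsAsFactors = FALSE)
  }

  frontier <- list()
  for (s in seeds) {
    stopifnot(inherits(s, "source_document"))
    rec <- get_record(index, s$doc_id)
    if (!is.null(rec)) visited[[record_dedup_key(rec)]] <- s$doc_id
    add_node(s$doc_id, "seed", 0L)
    frontier[[length(frontier) + 1L]] <- list(doc = s, depth = 0L,
                                              node_id = s$doc_id)
  }

  while (length(frontier)) {
    entry <- frontier[[1L]]
    frontier <- frontier[-1L]
    if (entry$depth >= max_depth) next
    doc <- entry$doc

    section <- tryCatch(
      locate_reference_section(doc, heading_lexicon = heading_lexicon),
      citesnow_section_not_found = function(e) NULL)
    if (is.null(section)) {
      add_unresolved(doc$doc_id, NA_integer_, "section_not_found")
      next
    }
    citations <- segment_references(section, footer_patterns = footer_patterns)

    for (i in seq_len(nrow(citations))) {
      cit <- citations[i, , drop = FALSE]
      query <- tryCatch(build_query(cit, min_len),
                        citesnow_empty_query = function(e) NULL)
      if (is.null(query)) {
        add_unresolved(cit$doc_id, cit$index, "empty_query")
        next
      }
      cand <- tryCatch(search_candidates(query, backend, k),
                       citesnow_backend = function(e) NULL)
      if (is.null(cand)) {
        add_unresolved(cit$doc_id, cit$index, "backend_error")
        next
      }
      dec <- decide_match(cand, tau, delta, doc_id = cit$doc_id,
                          index = cit$index)
      decisions[[length(decisions) + 1L]] <- dec
      if (dec$status != "matched") {
        add_unresolved(cit$doc_id, cit$index, dec$status)
        next
      }

      rec <- get_record(index, dec$matched_id)
      key <- record_dedup_key(rec)
      known <- visited[[key]]
      if (!is.null(known)) {
        add_edge(entry$node_id, known)
        next
      }
      child_depth <- entry$depth + 1L
      visited[[key]] <- rec$record_id
      add_node(rec$record_id, "record", child_depth)
      add_edge(entry$node_id, rec$record_id)

      if (!is.null(fetcher)) {
        out <- fetch_document(rec, fetcher)
        outcomes[[length(outcomes) + 1L]] <- data.frame(
          record_id = out$record_id, outcome = out$outcome,
          stringsAsFactors = FALSE)
        if (out$outcome == "full_text" && child_depth < max_depth) {
          child <- normalize_text(out$payload, rec$record_id)
          frontier[[length(frontier) + 1L]] <-
            list(doc = child, depth = child_depth, node_id = rec$record_id)
        }
      }
    }
  }

  edge_keys <- sort(ls(edges))
  edge_df <- if (length(edge_keys)) {
    parts <- strsplit(edge_keys, "\t", fixed = TRUE)
    data.frame(citing = vapply(parts, `[`, "", 1L),
               cited = vapply(parts, `[`, "", 2L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(citing = character(), cited = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(
    nodes = do.call(rbind, nodes),
    edges = edge_df,
    unresolved = if (length(unresolved)) do.call(rbind, unresolved) else
      data.frame(doc_id = character(), index = integer(),
                 status = character(), stringsAsFactors = FALSE),
    outcomes = if (length(outcomes)) do.call(rbind, outcomes) else
      data.frame(record_id = character(), outcome = character(),
                 stringsAsFactors = FALSE),
    decisions = decisions),
    class = "citation_graph")
}

#' @export
print.citation_graph <- function(x, ...) {
  cat(sprintf("<citation_graph: %d nodes (%d seeds), %d edges, %d unresolved citations>\n",
              nrow(x$nodes), sum(x$nodes$kind == "seed"), nrow(x$edges),
              nrow(x$unresolved)))
  if (nrow(x$nodes)) {
    depth_tab <- table(x$nodes$depth)
    cat("  nodes by depth:",
        paste(sprintf("d%s=%d", names(depth_tab), as.integer(depth_tab)),
              collapse = ", "), "\n")
  }
  if (nrow(x$outcomes)) {
    out_tab <- table(x$outcomes$outcome)
    cat("  retrieval:",
        paste(sprintf("%s=%d", names(out_tab), as.integer(out_tab)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a citation graph as JSON
#' @param graph A `citation_graph`.
#' @param path Output path.
#' @export
write_graph_json <- function(graph, path) {
  jsonlite::write_json(list(nodes = graph$nodes, edges = graph$edges,
                            unresolved = graph$unresolved,
                            outcomes = graph$outcomes),
                       path, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Write a citation graph's edge list as TSV
#' @param graph A `citation_graph`.
#' @param path Output path.
#' @export
write_edges_tsv <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
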