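#' Run the full pipeline on a synthetic corpus and evaluate it
#'
#' Convenience wrapper reproducing the evaluation protocol: snowball the
#' corpus seeds at depth 1 (ingest, segment, query, match, fetch; no
#' recursion, matching the single-level evaluation design), then score the
#' run against the corpus gold standard.
#'
#' @param corpus A `synthetic_corpus`.
#' @param ... Passed to [snowball()] (`tau`, `delta`, `k`, `min_len`, ...).
#' @return List with `graph` (the `citation_graph`) and `report` (the
#'   `evaluation_report`).
#' @export
#' @examples
#' corpus <- generate_corpus(corpus_spec(n_records = 60, n_seed_articles = 2,
#'                                       refs_per_article = c(5, 8),
#'                                       seed = 7))
#' res <- run_corpus_evaluation(corpus)
#' res$report
run_corpus_evaluation <- function(corpus, ...) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  seeds <- corpus_seed_documents(corpus)
  graph <- snowball(seeds, corpus$index,
                    fetcher = store_fetcher(corpus$store),
                    max_depth = 1L, ...)
  report <- evaluate_run(graph$decisions, graph$outcomes, corpus$gold)
  list(graph = graph, report = report)
}

#' Per-document segmentation recall on a synthetic corpus
#'
#' Runs section location and segmentation over every article and scores each
#' extracted string against the gold reference with the strict criterion:
#' correct only if the entire reference is present with nothing from other
#' citations, footers or body text (label and whitespace differences are
#' allowed; comparison is via [normalize_citation()]).
#'
#' @param corpus A `synthetic_corpus`.
#' @return List with `recall` (overall fraction of gold citations correctly
#'   extracted), `n_gold`, `n_correct`, and `per_document` data.frame.
#' @export
segmentation_recall <- function(corpus) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  per_doc <- lapply(corpus$articles, function(a) {
    doc <- normalize_text(a$text, a$doc_id)
    got <- tryCatch({
      section <- locate_reference_section(doc)
      segment_references(section)
    }, citesnow_error = function(e) empty_citations(a$doc_id))
    gold_norm <- normalize_citation(a$citations$raw)
    got_norm <- normalize_citation(got$raw)
    data.frame(doc_id = a$doc_id, n_gold = length(gold_norm),
               n_correct = sum(gold_norm %in% got_norm),
               stringsAsFactors = FALSE)
  })
  per_doc <- do.call(rbind, per_doc)
  list(recall = sum(per_doc$n_correct) / sum(per_doc$n_gold),
       n_gold = sum(per_doc$n_gold), n_correct = sum(per_doc$n_correct),
       per_document = per_doc)
}
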