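#' Precision, recall and F1
#'
#' The standard retrieval formulas: precision = TP / (TP + FP),
#' recall = TP / (TP + FN), F1 = 2PR / (P + R). Empty denominators give 0
#' (an empty system-positive or gold-positive set earns no credit).
#'
#' @param tp,fp,fn Non-negative counts (vectorized).
#' @param p,r Precision and recall in `[0, 1]`.
#' @return Numeric value(s) in `[0, 1]`.
#' @export
precision <- function(tp, fp) {
  ifelse(tp + fp == 0, 0, tp / (tp + fp))
}

#' @rdname precision
#' @export
recall <- function(tp, fn) {
  ifelse(tp + fn == 0, 0, tp / (tp + fn))
}

#' @rdname precision
#' @export
f1 <- function(p, r) {
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

eval_stages <- function() c("citations_retrieved", "abstracts_fetched",
                            "fulltext_fetched")
eval_denominators <- function() c("all", "included", "indexed")

#' Coerce engine decisions to a flat table
#' @param decisions List of `match_decision` objects (e.g.
#'   `graph$decisions`), or an already-flat data.frame.
#' @return data.frame with `doc_id`, `index`, `matched_id`, `score`,
#'   `margin`, `status`.
#' @export
decisions_table <- function(decisions) {
  if (is.data.frame(decisions)) return(decisions)
  do.call(rbind, lapply(decisions, function(d) {
    data.frame(doc_id = d$doc_id, index = d$index,
               matched_id = d$matched_id, score = d$score,
               margin = d$margin, status = d$status,
               stringsAsFactors = FALSE)
  }))
}

#' Read / write a gold standard as JSON lines
#'
#' One object per citation: `doc_id`, `index`, `true_record_id` (null for
#' citations with no true record in the index), `included` (false for
#' websites, books, book chapters, newspaper articles and grey literature)
#' and `indexed` (true when the cited work is present in the backend index;
#' implies `included`).
#'
#' @param path File path.
#' @return data.frame with the columns above.
#' @export
read_gold <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  do.call(rbind, lapply(lines, function(l) {
    g <- jsonlite::fromJSON(l)
    data.frame(doc_id = g$doc_id, index = as.integer(g$index),
               true_record_id = if (is.null(g$true_record_id))
                 NA_character_ else g$true_record_id,
               included = isTRUE(g$included), indexed = isTRUE(g$indexed),
               stringsAsFactors = FALSE)
  }))
}

#' @rdname read_gold
#' @param gold Gold-standard data.frame.
#' @export
write_gold <- function(gold, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(gold))) {
    writeLines(jsonlite::toJSON(list(
      doc_id = gold$doc_id[i], index = gold$index[i],
      true_record_id = if (is.na(gold$true_record_id[i])) NULL else
        gold$true_record_id[i],
      included = gold$included[i], indexed = gold$indexed[i]),
      auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' Evaluate a snowballing run against a gold standard
#'
#' Computes confusion counts and precision/recall/F1 for three stages
#' (citations retrieved, abstracts fetched — abstracts alone or with full
#' text —, full text fetched) crossed with three gold denominators: all
#' citations, included citations (websites, books, book chapters, newspaper
#' articles and grey literature excluded), and included citations present in
#' the backend index.
#'
#' For each denominator, both the gold-positive set and the system-positive
#' set are restricted to citations inside it, so precision is constant
#' across denominators whenever every system positive cites an
#' included-and-indexed work. A citation counts as a true positive at the
#' citation stage when the accepted record is the annotated one; at the
#' abstract stage when, additionally, its abstract or full text was
#' retrieved; at the full-text stage when its full text was retrieved.
#'
#' @param decisions List of `match_decision`s or the data.frame from
#'   [decisions_table()]. Citations absent from `decisions` (e.g. empty
#'   queries) simply count as not retrieved.
#' @param outcomes data.frame `record_id`, `outcome` (e.g.
#'   `graph$outcomes`); may be empty if retrieval was not run.
#' @param gold Gold-standard data.frame, see [read_gold()]. Must cover every
#'   citation appearing in `decisions`.
#' @return An object of class `evaluation_report`: data.frame with one row
#'   per stage x denominator (`stage`, `denominator`, `n_gold`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f1`).
#' @export
evaluate_run <- function(decisions, outcomes, gold) {
  dec <- decisions_table(decisions)
  if (is.null(dec)) {
    dec <- data.frame(doc_id = character(), index = integer(),
                      matched_id = character(), status = character(),
                      stringsAsFactors = FALSE)
  }
  key <- function(d, i) paste(d, i, sep = "#")
  gold_keys <- key(gold$doc_id, gold$index)
  missing <- setdiff(key(dec$doc_id, dec$index), gold_keys)
  if (length(missing)) {
    stop_citesnow("missing_annotation",
                  sprintf("no gold annotation for citation(s): %s",
                          paste(missing, collapse = ", ")))
  }

  dec <- dec[dec$status == "matched", , drop = FALSE]
  dec$gold_row <- match(key(dec$doc_id, dec$index), gold_keys)
  dec$correct <- !is.na(gold$true_record_id[dec$gold_row]) &
    dec$matched_id == gold$true_record_id[dec$gold_row]
  fetched <- outcomes$record_id[outcomes$outcome %in%
                                  c("full_text", "abstract_only")]
  fulltext <- outcomes$record_id[outcomes$outcome == "full_text"]

  rows <- list()
  for (denom in eval_denominators()) {
    in_denom <- switch(denom,
                       all = rep(TRUE, nrow(gold)),
                       included = gold$included,
                       indexed = gold$included & gold$indexed)
    n_gold <- sum(in_denom)
    d <- dec[in_denom[dec$gold_row], , drop = FALSE]
    for (stage in eval_stages()) {
      pos <- switch(stage,
                    citations_retrieved = d,
                    abstracts_fetched = d[d$matched_id %in% fetched, ,
                                          drop = FALSE],
                    fulltext_fetched = d[d$matched_id %in% fulltext, ,
                                         drop = FALSE])
      tp <- sum(pos$correct)
      fp <- nrow(pos) - tp
      fn <- n_gold - tp
      p <- precision(tp, fp)
      r <- recall(tp, fn)
      rows[[length(rows) + 1L]] <- data.frame(
        stage = stage, denominator = denom, n_gold = n_gold,
        tp = tp, fp = fp, fn = fn,
        precision = p, recall = r, f1 = f1(p, r),
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("evaluation_report",
                                            "data.frame"))
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat("Evaluation report (precision / recall / F1)\n")
  denoms <- eval_denominators()
  hdr <- vapply(denoms, function(d) {
    n <- x$n_gold[x$denominator == d][1]
    sprintf("%s (n=%d)", d, n)
  }, character(1))
  cat(sprintf("%-22s %18s %18s %18s\n", "", hdr[1], hdr[2], hdr[3]))
  for (stage in eval_stages()) {
    cat(stage, "\n")
    for (metric in c("precision", "recall", "f1")) {
      vals <- vapply(denoms, function(d) {
        x[[metric]][x$stage == stage & x$denominator == d]
      }, numeric(1))
      cat(sprintf("  %-20s %18.3f %18.3f %18.3f\n", metric,
                  vals[1], vals[2], vals[3]))
    }
  }
  invisible(x)
}

#' Write an evaluation report as a TSV table
#'
#' Layout: three stage blocks, each with precision / recall / F1 rows at
#' three decimals across the three denominator columns.
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @export
write_report_tsv <- function(report, path) {
  denoms <- eval_denominators()
  lines <- c(paste(c("metric", vapply(denoms, function(d) {
    sprintf("%s_n%d", d, report$n_gold[report$denominator == d][1])
  }, character(1))), collapse = "\t"))
  for (stage in eval_stages()) {
    lines <- c(lines, stage)
    for (metric in c("precision", "recall", "f1")) {
      vals <- vapply(denoms, function(d) {
        report[[metric]][report$stage == stage & report$denominator == d]
      }, numeric(1))
      lines <- c(lines, paste(c(metric, sprintf("%.3f", vals)),
                              collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
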