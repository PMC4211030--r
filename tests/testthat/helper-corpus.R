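# Shared fixtures, built in code.

small_spec <- function(seed = 7, ...) {
  corpus_spec(n_records = 120, n_seed_articles = 5,
              refs_per_article = c(8, 14), seed = seed, ...)
}

# cache corpora across tests within a file run
.corpus_cache <- new.env(parent = emptyenv())
cached_corpus <- function(key, spec) {
  if (is.null(.corpus_cache[[key]])) {
    .corpus_cache[[key]] <- generate_corpus(spec)
  }
  .corpus_cache[[key]]
}

# an article-shaped text: filler body (padded past the reference block),
# a References heading, then the given reference lines
make_article_text <- function(ref_lines, body_word = "lorem") {
  block <- paste(ref_lines, collapse = "\n")
  body <- paste(rep(body_word, max(60, ceiling((nchar(block) + 120) / 6))),
                collapse = " ")
  paste0(body, ".\n\nReferences\n", block)
}

# hand-built record for engine/search tests
make_record <- function(id, title, cited = character(0),
                        year = 2005, doi = NA_character_,
                        urls = list(list(url = paste0("u://", id, "/full"),
                                         kind = "fulltext"))) {
  list(record_id = id, title = title,
       authors = c("Tester AB"), venue = "Journal of Handmade Fixtures",
       year = year, doi = doi, urls = urls, cited_ids = cited)
}

# fixture store whose full-text payload for each record is an article citing
# the record's cited_ids (rendered dot-number style)
make_tree_store <- function(index) {
  entries <- list()
  for (id in index$ids) {
    rec <- index$records[[id]]
    cites <- vapply(seq_along(rec$cited_ids), function(k) {
      render_citation(index$records[[rec$cited_ids[k]]], "dot_number", k)
    }, "")
    text <- if (length(cites)) make_article_text(cites) else
      make_article_text("")
    entries[[paste0("u://", id, "/full")]] <-
      list(payload = text, kind = "fulltext")
  }
  fixture_store(entries)
}

# distinct multi-word titles for hand-built indexes (every word >= 4 letters)
handmade_titles <- function(n) {
  words <- c("quantum", "flux", "modulation", "neural", "viral", "kinetic",
             "resistance", "surveillance", "genomic", "spectral", "thermal",
             "oscillation", "membrane", "protein", "catalytic", "dynamics",
             "inhibitor", "clearance", "response", "profile")
  combos <- utils::combn(words, 3)  # distinct word sets: none subsumes another
  stopifnot(n <= ncol(combos))
  apply(combos[, seq_len(n), drop = FALSE], 2, paste, collapse = " ")
}
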