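#' Build a normalized search query from a citation string
#'
#' Applies the query-normalization rule: tokenize on non-letter boundaries
#' (digits, punctuation and hyphens act as separators, so numbers vanish and
#' hyphenated words split), drop tokens with fewer than `min_len` letters,
#' and lowercase the survivors. Order is preserved and duplicates are kept.
#' Non-ASCII letters survive (author names) and are case-folded
#' locale-independently.
#'
#' @param citation A single-row citation data.frame from
#'   [segment_references()], or a character scalar (the raw reference string).
#' @param min_len Minimum token length in letters; shorter tokens ("et",
#'   "al", initials, most stopwords) are dropped. Default 4.
#' @return An object of class `search_query`: list with `doc_id`, `index`
#'   and `tokens` (ordered character vector).
#' @section Errors: if every token is removed, an `empty_query` error is
#'   signalled -- such a citation is reported unresolvable, never searched.
#' @export
#' @examples
#' q <- build_query("12. Smith J, et al. Oseltamivir resistance surveillance.
#'                   Lancet. 2009;373:1175-6.")
#' q$tokens
build_query <- function(citation, min_len = 4L) {
  if (is.character(citation)) {
    citation <- data.frame(doc_id = NA_character_, index = NA_integer_,
                           raw = citation, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(citation), nrow(citation) == 1L,
            nzchar(citation$raw))
  tokens <- tokenize_letters(citation$raw, min_len)
  if (!length(tokens)) {
    stop_citesnow("empty_query",
                  sprintf("citation %s#%s reduces to an empty query",
                          citation$doc_id, citation$index),
                  doc_id = citation$doc_id, index = citation$index)
  }
  structure(list(doc_id = citation$doc_id, index = citation$index,
                 tokens = tokens),
            class = "search_query")
}

# letter-run tokenization shared by queries and index records
tokenize_letters <- function(x, min_len = 1L) {
  tokens <- stringi::stri_extract_all_regex(x, "\\p{L}+")[[1]]
  tokens <- tokens[!is.na(tokens)]
  tokens <- tokens[nchar(tokens) >= min_len]
  stringi::stri_trans_tolower(tokens)
}

#' Build queries for a whole citation table
#'
#' Vectorized wrapper over [build_query()]; citations whose query would be
#' empty are returned with status `"empty_query"` instead of erroring.
#'
#' @param citations Citation data.frame from [segment_references()].
#' @param min_len See [build_query()].
#' @return A list with `queries` (list of `search_query`) and `unresolvable`
#'   (data.frame of doc_id/index that produced empty queries).
#' @export
build_queries <- function(citations, min_len = 4L) {
  queries <- list()
  bad <- list()
  for (i in seq_len(nrow(citations))) {
    q <- tryCatch(build_query(citations[i, , drop = FALSE], min_len),
                  citesnow_empty_query = function(e) e)
    if (inherits(q, "search_query")) {
      queries[[length(queries) + 1L]] <- q
    } else {
      bad[[length(bad) + 1L]] <- data.frame(
        doc_id = citations$doc_id[i], index = citations$index[i],
        stringsAsFactors = FALSE)
    }
  }
  list(queries = queries,
       unresolvable = if (length(bad)) do.call(rbind, bad) else
         data.frame(doc_id = character(), index = integer(),
                    stringsAsFactors = FALSE))
}

#' @export
print.search_query <- function(x, ...) {
  cat(sprintf("<search_query %s#%s: %s>\n", x$doc_id, x$index,
              paste(x$tokens, collapse = " ")))
  invisible(x)
}
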