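#' Construct a bibliographic index from a list of records
#'
#' Validates record invariants and precomputes the token statistics
#' (document frequencies, postings) used for rarity-weighted matching.
#'
#' @param records List of bibliographic records. Each record is a list with
#'   `record_id`, `title`, `authors` (character vector), `venue`, `year`,
#'   optional `doi`, `urls` (list of `list(url, kind)` with kind one of
#'   `landing`, `fulltext`, `abstract`), optional `abstract_ref`,
#'   `fulltext_ref`, and `cited_ids` (character vector).
#' @return An object of class `bib_index`.
#' @export
bib_index <- function(records) {
  stopifnot(is.list(records))
  ids <- vapply(records, function(r) as.character(r$record_id), character(1))
  if (anyDuplicated(ids)) {
    stop_citesnow("invalid_index", "duplicate record_id in index")
  }
  years <- vapply(records, function(r) as.integer(r$year), integer(1))
  if (any(!is.na(years) & (years < 1800L | years > 2100L))) {
    stop_citesnow("invalid_index", "record year outside [1800, 2100]")
  }
  dois <- tolower(vapply(records, function(r)
    if (is.null(r$doi) || is.na(r$doi)) "" else as.character(r$doi),
    character(1)))
  if (anyDuplicated(dois[nzchar(dois)])) {
    stop_citesnow("invalid_index", "duplicate DOI (case-insensitive) in index")
  }
  names(records) <- ids

  # token multiset of the searchable field: title + authors + venue
  tokens <- lapply(records, function(r) {
    unique(tokenize_letters(paste(r$title, paste(r$authors, collapse = " "),
                                  r$venue)))
  })
  postings <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(tokens)) {
    for (t in tokens[[i]]) {
      postings[[t]] <- c(postings[[t]], i)
    }
  }
  structure(list(records = records, ids = ids, tokens = tokens,
                 postings = postings, n = length(records)),
            class = "bib_index")
}

#' Read a bibliographic index from a JSON-lines file
#'
#' One record per line; field names as documented in [bib_index()].
#'
#' @param path Path to a `.jsonl` file.
#' @return A `bib_index`.
#' @export
read_bib_index <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  records <- lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l, simplifyDataFrame = FALSE)
    r$authors <- as.character(unlist(r$authors))
    r$cited_ids <- as.character(unlist(r$cited_ids))
    r
  })
  bib_index(records)
}

#' Write a bibliographic index to a JSON-lines file
#' @param index A `bib_index`.
#' @param path Output path.
#' @export
write_bib_index <- function(index, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (r in index$records) {
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' Fetch one record from an index by id
#' @param index A `bib_index`.
#' @param record_id Record identifier.
#' @return The record, or `NULL` when absent.
#' @export
get_record <- function(index, record_id) {
  index$records[[as.character(record_id)]]
}

#' Inverse-document-frequency weights for query tokens
#'
#' Smoothed IDF over the backing index:
#' `w(t) = log((N + 1) / (df(t) + 1)) + 1`, which is positive for every
#' token (including tokens absent from the index, which get the maximal
#' weight) and equal for tokens of equal document frequency.
#'
#' @param index A `bib_index`.
#' @param tokens Character vector of query tokens.
#' @return Numeric vector of weights, one per token occurrence.
#' @export
idf_weights <- function(index, tokens) {
  df <- vapply(tokens, function(t) {
    p <- index$postings[[t]]
    if (is.null(p)) 0L else length(p)
  }, integer(1))
  log((index$n + 1) / (df + 1)) + 1
}

#' Score one record against a query
#'
#' Rarity-weighted token overlap: the summed weight of query tokens present
#' in the record's concatenated title + authors + venue field, divided by the
#' total query weight. 1 when every token is present, 0 when none is.
#' With uniform weights this is the fraction of query tokens found.
#'
#' @param tokens Character vector of query tokens (a `search_query$tokens`).
#' @param record A bibliographic record.
#' @param weights Numeric vector of per-token weights; `NULL` means uniform.
#' @return A number in `[0, 1]`.
#' @export
score_candidate <- function(tokens, record, weights = NULL) {
  if (inherits(tokens, "search_query")) tokens <- tokens$tokens
  if (!length(tokens)) return(0)
  if (is.null(weights)) weights <- rep(1, length(tokens))
  stopifnot(length(weights) == length(tokens))
  field <- tokenize_letters(paste(record$title,
                                  paste(record$authors, collapse = " "),
                                  record$venue))
  sum(weights[tokens %in% field]) / sum(weights)
}

#' Local deterministic search backend over a bibliographic index
#'
#' The backend contract is a list with a `search(tokens, k)` element
#' returning at most `k` candidates sorted by descending score with ties
#' broken by ascending record id. This implementation scores every record in
#' the index via its token postings; it is exactly equivalent to exhaustively
#' applying [score_candidate()] with [idf_weights()] to all records.
#'
#' @param index A `bib_index`.
#' @return An object of class `snowball_backend`.
#' @export
local_backend <- function(index) {
  stopifnot(inherits(index, "bib_index"))
  structure(list(
    index = index,
    search = function(tokens, k = 5L) {
      w <- idf_weights(index, tokens)
      scores <- numeric(index$n)
      for (j in seq_along(tokens)) {
        hits <- index$postings[[tokens[j]]]
        if (!is.null(hits)) scores[hits] <- scores[hits] + w[j]
      }
      scores <- scores / sum(w)
      pos <- which(scores > 0)
      if (!length(pos)) {
        return(data.frame(record_id = character(), score = numeric(),
                          stringsAsFactors = FALSE))
      }
      ord <- pos[order(-scores[pos], index$ids[pos])]
      ord <- utils::head(ord, k)
      data.frame(record_id = index$ids[ord], score = scores[ord],
                 stringsAsFactors = FALSE)
    }), class = "snowball_backend")
}

#' Skeleton HTTP search-backend adapter
#'
#' Illustrates how a live bibliographic API satisfies the backend contract:
#' supply `request_fn(tokens, k)` performing the HTTP round trip and
#' returning a data.frame of `record_id`, `score`. No live client ships with
#' the package; calling the default signals a backend error.
#'
#' @param request_fn Function `(tokens, k) -> data.frame(record_id, score)`.
#' @return A `snowball_backend`.
#' @export
http_backend <- function(request_fn = NULL) {
  structure(list(
    search = function(tokens, k = 5L) {
      if (is.null(request_fn)) {
        stop_citesnow("backend", "http_backend has no request function configured")
      }
      res <- request_fn(tokens, k)
      res[order(-res$score, res$record_id), , drop = FALSE]
    }), class = "snowball_backend")
}

#' Search a backend for a query
#'
#' @param query A `search_query`.
#' @param backend A `snowball_backend`.
#' @param k Maximum number of candidates.
#' @return Candidate data.frame (`record_id`, `score`), best first.
#' @section Errors: backend failures raise a `backend` error carrying the
#'   query's citation reference; callers mark the citation unresolved and
#'   continue.
#' @export
search_candidates <- function(query, backend, k = 5L) {
  stopifnot(inherits(query, "search_query"),
            inherits(backend, "snowball_backend"))
  tryCatch(backend$search(query$tokens, k),
           error = function(e) {
             if (inherits(e, "citesnow_backend")) {
               stop_citesnow("backend", conditionMessage(e),
                             doc_id = query$doc_id, index = query$index)
             }
             stop_citesnow("backend",
                           sprintf("backend failure for %s#%s: %s",
                                   query$doc_id, query$index,
                                   conditionMessage(e)),
                           doc_id = query$doc_id, index = query$index)
           })
}

#' Accept or reject the top search candidate
#'
#' Conservative acceptance: the top candidate is taken as the cited work only
#' when its score clears `tau` and it beats the runner-up by at least
#' `delta` (a lone candidate has no runner-up to beat). Everything else is
#' explicitly labelled, so downstream evaluation can distinguish "nothing
#' found", "too weak" and "ambiguous".
#'
#' @param candidates Candidate data.frame from [search_candidates()].
#' @param tau Score threshold, default 0.7.
#' @param delta Required score margin over the runner-up, default 0.05.
#' @param doc_id,index Citation reference carried into the decision.
#' @return An object of class `match_decision`: list with `doc_id`, `index`,
#'   `matched_id` (or `NA`), `score`, `margin`, `status` in
#'   `matched`, `no_candidates`, `below_threshold`, `ambiguous`.
#' @export
decide_match <- function(candidates, tau = 0.7, delta = 0.05,
                         doc_id = NA_character_, index = NA_integer_) {
  mk <- function(status, matched_id = NA_character_, score = NA_real_,
                 margin = NA_real_) {
    structure(list(doc_id = doc_id, index = index, matched_id = matched_id,
                   score = score, margin = margin, status = status),
              class = "match_decision")
  }
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return(mk("no_candidates"))
  }
  top <- candidates$score[1]
  margin <- if (nrow(candidates) == 1L) top else top - candidates$score[2]
  if (top < tau) {
    return(mk("below_threshold", score = top, margin = margin))
  }
  if (nrow(candidates) > 1L && margin < delta) {
    return(mk("ambiguous", score = top, margin = margin))
  }
  mk("matched", matched_id = candidates$record_id[1], score = top,
     margin = margin)
}

#' @export
print.match_decision <- function(x, ...) {
  cat(sprintf("<match_decision %s#%s: %s%s score=%.3f margin=%.3f>\n",
              x$doc_id, x$index, x$status,
              if (!is.na(x$matched_id)) paste0(" -> ", x$matched_id) else "",
              if (is.na(x$score)) 0 else x$score,
              if (is.na(x$margin)) 0 else x$margin))
  invisible(x)
}

#' Deduplication key for a bibliographic record
#'
#' Records discovered via different routes (multiple versions of the same
#' work) collapse onto one node: the case-folded DOI when present, otherwise
#' the lowercased letters of the title plus the year.
#'
#' @param record A bibliographic record.
#' @return Character scalar key.
#' @export
record_dedup_key <- function(record) {
  doi <- record$doi
  if (!is.null(doi) && !is.na(doi) && nzchar(doi)) {
    return(paste0("doi:", tolower(doi)))
  }
  paste0("ty:", paste(tokenize_letters(record$title), collapse = ""),
         ":", record$year)
}

#' Export records as RIS
#' @param records List of bibliographic records.
#' @param path Output path.
#' @export
write_ris <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (r in records) {
    writeLines("TY  - JOUR", con)
    for (a in r$authors) writeLines(paste0("AU  - ", a), con)
    writeLines(paste0("TI  - ", r$title), con)
    writeLines(paste0("JO  - ", r$venue), con)
    writeLines(paste0("PY  - ", r$year), con)
    if (!is.null(r$doi) && !is.na(r$doi) && nzchar(r$doi)) {
      writeLines(paste0("DO  - ", r$doi), con)
    }
    writeLines(paste0("ID  - ", r$record_id), con)
    writeLines("ER  - ", con)
    writeLines("", con)
  }
  invisible(path)
}

#' Export records as BibTeX
#' @param records List of bibliographic records.
#' @param path Output path.
#' @export
write_bibtex <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (r in records) {
    key <- gsub("[^A-Za-z0-9]", "", r$record_id)
    writeLines(sprintf("@article{%s,", key), con)
    writeLines(sprintf("  author = {%s},",
                       paste(r$authors, collapse = " and ")), con)
    writeLines(sprintf("  title = {%s},", r$title), con)
    writeLines(sprintf("  journal = {%s},", r$venue), con)
    writeLines(sprintf("  year = {%s}%s", r$year,
                       if (!is.null(r$doi) && !is.na(r$doi) && nzchar(r$doi))
                         "," else ""), con)
    if (!is.null(r$doi) && !is.na(r$doi) && nzchar(r$doi)) {
      writeLines(sprintf("  doi = {%s}", r$doi), con)
    }
    writeLines("}", con)
    writeLines("", con)
  }
  invisible(path)
}

#' @export
print.bib_index <- function(x, ...) {
  cat(sprintf("<bib_index: %d records, %d distinct tokens>\n",
              x$n, length(ls(x$postings))))
  invisible(x)
}
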