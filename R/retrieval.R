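#' In-memory fixture store for link resolution
#'
#' Maps a URL to either a payload (the document content, with a kind tag) or
#' a failure annotation from the retrieval taxonomy. The shipped fetcher
#' reads from such a store, which makes every retrieval outcome reproducible
#' offline; a live HTTP fetcher can satisfy the same contract.
#'
#' @param entries Named list keyed by URL. Each entry is a list with either
#'   `payload` (character content) and `kind` (`"fulltext"` or `"abstract"`),
#'   or `failure` in `"broken_link"`, `"dynamic_link_unresolved"`,
#'   `"access_denied"`.
#' @return An object of class `fixture_store`.
#' @export
fixture_store <- function(entries = list()) {
  structure(list(entries = entries), class = "fixture_store")
}

#' Read a fixture store from a directory
#'
#' Expects `manifest.json` mapping URL to `{payload: file, kind: tag}` or
#' `{failure: tag}`, with payload files resolved relative to the directory.
#'
#' @param dir Directory path.
#' @return A `fixture_store`.
#' @export
read_fixture_store <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = FALSE)
  entries <- lapply(manifest, function(e) {
    if (!is.null(e$payload)) {
      p <- file.path(dir, e$payload)
      list(payload = readChar(p, file.size(p), useBytes = TRUE),
           kind = e$kind)
    } else {
      list(failure = e$failure)
    }
  })
  fixture_store(entries)
}

#' Write a fixture store to a directory
#' @param store A `fixture_store`.
#' @param dir Output directory (created if missing).
#' @export
write_fixture_store <- function(store, dir) {
  dir.create(file.path(dir, "payloads"), recursive = TRUE,
             showWarnings = FALSE)
  manifest <- list()
  i <- 0L
  for (url in names(store$entries)) {
    e <- store$entries[[url]]
    if (!is.null(e$payload)) {
      i <- i + 1L
      fn <- file.path("payloads", sprintf("p%05d.txt", i))
      writeLines(e$payload, file.path(dir, fn), useBytes = TRUE)
      manifest[[url]] <- list(payload = fn, kind = e$kind)
    } else {
      manifest[[url]] <- list(failure = e$failure)
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Fetcher over a fixture store
#'
#' The fetcher contract: a function `url -> list(status, content, kind)`
#' where `status` is `"ok"` or a failure tag (`"broken_link"`,
#' `"dynamic_link_unresolved"`, `"access_denied"`). Unknown URLs are broken
#' links (the index pointed somewhere that does not resolve).
#'
#' @param store A `fixture_store`.
#' @return A function satisfying the fetcher contract.
#' @export
store_fetcher <- function(store) {
  stopifnot(inherits(store, "fixture_store"))
  function(url) {
    e <- store$entries[[url]]
    if (is.null(e)) {
      return(list(status = "broken_link", content = NULL, kind = NULL))
    }
    if (!is.null(e$failure)) {
      return(list(status = e$failure, content = NULL, kind = NULL))
    }
    list(status = "ok", content = e$payload, kind = e$kind)
  }
}

retrieval_outcomes <- function() {
  c("full_text", "abstract_only", "no_link", "broken_link",
    "dynamic_link_unresolved", "access_denied")
}

#' Follow a record's links and classify the retrieval outcome
#'
#' URLs are tried in kind priority full text > abstract > landing. A URL
#' whose payload is full text decides the outcome immediately as
#' `full_text`; an abstract payload is kept as fallback while remaining URLs
#' are tried, so full text wins whenever any link yields it. When nothing
#' yields content, the outcome is the failure class of the
#' highest-priority link (or `no_link` when the record carries no URLs at
#' all). Network-class failures are outcomes, never errors.
#'
#' @param record A bibliographic record.
#' @param fetcher A fetcher function, e.g. from [store_fetcher()].
#' @return An object of class `retrieval_outcome`: list with `record_id`,
#'   `outcome`, `payload` (content for `full_text` / `abstract_only`, else
#'   `NULL`) and `url` (the decisive URL, or `NA`).
#' @export
fetch_document <- function(record, fetcher) {
  stopifnot(is.function(fetcher))
  mk <- function(outcome, payload = NULL, url = NA_character_) {
    structure(list(record_id = record$record_id, outcome = outcome,
                   payload = payload, url = url),
              class = "retrieval_outcome")
  }
  urls <- record$urls
  if (is.null(urls) || !length(urls)) return(mk("no_link"))

  kinds <- vapply(urls, function(u) u$kind %||% "landing", character(1))
  prio <- match(kinds, c("fulltext", "abstract", "landing"))
  urls <- urls[order(prio)]

  abstract_hit <- NULL
  first_failure <- NULL
  for (u in urls) {
    res <- fetcher(u$url)
    if (!is.list(res) || is.null(res$status)) {
      stop_citesnow("fetcher_contract",
                    "fetcher must return list(status, content, kind)")
    }
    if (res$status == "ok") {
      kind <- res$kind %||% (u$kind %||% "fulltext")
      if (kind == "abstract") {
        if (is.null(abstract_hit)) {
          abstract_hit <- mk("abstract_only", payload = res$content,
                             url = u$url)
        }
      } else {
        return(mk("full_text", payload = res$content, url = u$url))
      }
    } else {
      if (!res$status %in% c("broken_link", "dynamic_link_unresolved",
                             "access_denied")) {
        stop_citesnow("fetcher_contract",
                      sprintf("unknown fetcher status '%s'", res$status))
      }
      if (is.null(first_failure)) {
        first_failure <- mk(res$status, url = u$url)
      }
    }
  }
  if (!is.null(abstract_hit)) return(abstract_hit)
  first_failure
}

#' @export
print.retrieval_outcome <- function(x, ...) {
  cat(sprintf("<retrieval_outcome %s: %s%s>\n", x$record_id, x$outcome,
              if (!is.null(x$payload))
                sprintf(" (%d chars)", nchar(x$payload)) else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
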