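#' Normalize raw article text into a source document
#'
#' Decodes input as UTF-8 (invalid bytes become the Unicode replacement
#' character), applies compatibility normalization (NFKC) and unifies line
#' endings to `"\n"`. This is the canonical entry point for text produced by
#' an external PDF or HTML converter: everything downstream (section
#' location, segmentation) assumes a document produced here.
#'
#' @param raw A character scalar or a raw vector holding the article text.
#' @param doc_id Opaque document identifier, unique within a run.
#' @param origin One of `"plain"`, `"converted_pdf"`, `"converted_html"`.
#' @return An object of class `source_document`: a list with `doc_id`,
#'   `text` and `origin`.
#' @export
#' @examples
#' doc <- normalize_text("Intro.\r\nReferences\r\n1. A citation.", "d1")
#' doc$text
normalize_text <- function(raw, doc_id, origin = c("plain", "converted_pdf",
                                                   "converted_html")) {
  origin <- match.arg(origin)
  if (is.raw(raw)) {
    raw <- rawToChar(raw)
    Encoding(raw) <- "UTF-8"
  }
  stopifnot(is.character(raw))
  text <- paste(raw, collapse = "\n")
  text <- stringi::stri_enc_toutf8(text, validate = TRUE)
  text <- stringi::stri_trans_nfkc(text)
  text <- gsub("\r\n?", "\n", text)
  if (!nzchar(trimws(text))) {
    stop_citesnow("empty_document",
                  sprintf("document '%s' is empty after normalization", doc_id))
  }
  structure(list(doc_id = as.character(doc_id), text = text, origin = origin),
            class = "source_document")
}

#' Read a document from a plain-text file
#'
#' For PDF/HTML sources, pass an `adapter` callable (path -> text) wrapping an
#' external converter; conversion itself is out of scope here.
#'
#' @param path File path.
#' @param doc_id Identifier; defaults to the file name without extension.
#' @param origin Origin tag, see [normalize_text()].
#' @param adapter Optional function `path -> character` used instead of
#'   reading the file as UTF-8 text.
#' @return A `source_document`.
#' @export
read_document <- function(path, doc_id = NULL, origin = "plain",
                          adapter = NULL) {
  if (is.null(doc_id)) doc_id <- sub("\\.[^.]*$", "", basename(path))
  txt <- if (is.null(adapter)) {
    readChar(path, file.size(path), useBytes = TRUE)
  } else {
    adapter(path)
  }
  normalize_text(txt, doc_id, origin)
}

#' Default reference-section heading lexicon
#'
#' Headings are matched case-insensitively at the start of a line.
#' @return Character vector of heading strings.
#' @export
default_heading_lexicon <- function() {
  c("References", "Bibliography", "Literature Cited", "Reference List")
}

#' Default stop-headings that truncate a reference section
#' @return Character vector of heading strings.
#' @export
default_stop_headings <- function() {
  c("Appendix", "Supplementary Material", "Supplementary Information")
}

#' Locate the reference section of a document
#'
#' Scans for reference-list headings and keeps only those whose start offset
#' lies at or beyond the character midpoint of the text: reference lists
#' terminate articles, so a "References" mention in the first half is body
#' text, not the section heading. Among qualifying headings the last one
#' wins (appendices may repeat the word). The section extends from the
#' heading to the end of the document, or to the first stop-heading after it.
#'
#' @param doc A `source_document`.
#' @param heading_lexicon Character vector of heading strings, matched
#'   case-insensitively as whole lines (trailing punctuation tolerated).
#' @param stop_headings Character vector of headings that truncate the
#'   section; `character(0)` disables truncation.
#' @return An object of class `reference_section`: list with `doc_id`,
#'   `heading`, `start`, `end` (1-based inclusive offsets into `doc$text`)
#'   and `raw_text` (`substr(doc$text, start, end)`, heading line included).
#' @export
#' @examples
#' txt <- paste0(strrep("body text. ", 40), "\nReferences\n1. One citation.")
#' sec <- locate_reference_section(normalize_text(txt, "d1"))
#' sec$heading
locate_reference_section <- function(doc,
                                     heading_lexicon = default_heading_lexicon(),
                                     stop_headings = default_stop_headings()) {
  stopifnot(inherits(doc, "source_document"))
  text <- doc$text
  n <- nchar(text)
  midpoint <- floor(n / 2)

  hit <- find_headings(text, heading_lexicon)
  # the 50% rule: heading must start at or after the character midpoint
  hit <- hit[hit$start - 1L >= midpoint, , drop = FALSE]
  if (nrow(hit) == 0L) {
    stop_citesnow("section_not_found",
                  sprintf("no reference-section heading at or after the midpoint of document '%s'",
                          doc$doc_id))
  }
  hit <- hit[which.max(hit$start), ]

  end <- n
  if (length(stop_headings)) {
    stop_hit <- find_headings(text, stop_headings)
    stop_hit <- stop_hit[stop_hit$start > hit$end, , drop = FALSE]
    if (nrow(stop_hit) > 0L) end <- min(stop_hit$start) - 1L
  }

  structure(list(doc_id = doc$doc_id,
                 heading = hit$heading,
                 start = hit$start,
                 end = end,
                 raw_text = substr(text, hit$start, end)),
            class = "reference_section")
}

# Match lexicon entries as whole lines, case-insensitive, allowing optional
# leading section numbers ("7. References") and trailing ":" or ".".
find_headings <- function(text, lexicon) {
  out <- list()
  for (h in lexicon) {
    pat <- paste0("(?mi)^[ \t]*(?:\\d+\\.?[ \t]+)?",
                  stringi::stri_replace_all_regex(h, "([\\\\.^$|?*+()\\[\\]{}])", "\\\\$1"),
                  "[ \t]*[:.]?[ \t]*$")
    m <- stringi::stri_locate_all_regex(text, pat)[[1]]
    if (!all(is.na(m[, 1]))) {
      out[[length(out) + 1L]] <- data.frame(start = m[, 1], end = m[, 2],
                                            heading = h,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      heading = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' @export
print.source_document <- function(x, ...) {
  cat(sprintf("<source_document '%s' (%s), %d chars>\n",
              x$doc_id, x$origin, nchar(x$text)))
  invisible(x)
}

#' @export
print.reference_section <- function(x, ...) {
  cat(sprintf("<reference_section '%s': heading '%s' at %d..%d (%d chars)>\n",
              x$doc_id, x$heading, x$start, x$end, nchar(x$raw_text)))
  invisible(x)
}
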