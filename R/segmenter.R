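#' Default page-footer / running-head filter patterns
#'
#' Applied per line before segmentation; matching lines are treated as page
#' furniture (footers, running heads, bare page numbers) and dropped so they
#' cannot contaminate citation strings.
#'
#' @return Character vector of Perl regular expressions.
#' @export
default_footer_patterns <- function() {
  c("\\|",                                  # "Journal of X | Vol 3 | p. 12"
    "^[ \t]*\\d+[ \t]*$",                   # bare page number
    "^[ \t]*(?:Page|page|p\\.)[ \t]*\\d+[ \t]*$",
    "^[ \t]*(?:https?://|www\\.)\\S+[ \t]*$",
    "(?i)^[ \t]*downloaded from\\b")
}

label_patterns <- function() {
  c(bracket_number = "^[ \t]*\\[(\\d+)\\][ \t]*",
    dot_number     = "^[ \t]*(\\d+)\\.[ \t]+",
    paren_number   = "^[ \t]*\\((\\d+)\\)[ \t]*")
}

#' Detect the label style of a reference section
#'
#' Tries each numeric label pattern (`[1]`, `1.`, `(1)`) against the section
#' lines and measures the longest strictly increasing run of leading integers
#' starting at 1. The style with the longest run wins; if no numeric style
#' labels at least two lines, the section is taken to be author-year.
#'
#' @param section A `reference_section`.
#' @return One of `"bracket_number"`, `"dot_number"`, `"paren_number"`,
#'   `"author_year"`.
#' @export
detect_label_style <- function(section) {
  lines <- section_body_lines(section)$line
  best_style <- "author_year"
  best_run <- 1L
  for (style in names(label_patterns())) {
    pat <- label_patterns()[[style]]
    m <- stringi::stri_match_first_regex(lines, pat)[, 2]
    nums <- suppressWarnings(as.integer(m[!is.na(m)]))
    run <- increasing_run_from_one(nums)
    if (run > best_run) {
      best_run <- run
      best_style <- style
    }
  }
  if (best_run < 2L) "author_year" else best_style
}

# length of the longest strictly increasing run that starts at value 1
increasing_run_from_one <- function(nums) {
  if (!length(nums)) return(0L)
  best <- 0L
  run <- 0L
  prev <- NA_integer_
  for (v in nums) {
    if (is.na(v)) next
    if (v == 1L) {
      run <- 1L
    } else if (!is.na(prev) && run > 0L && v > prev) {
      run <- run + 1L
    } else if (run > 0L && (!is.na(prev)) && v <= prev) {
      run <- 0L
    }
    prev <- v
    best <- max(best, run)
  }
  best
}

#' Segment a reference section into citation strings
#'
#' Splits the section body into one string per cited work. Footer lines
#' matching `footer_patterns` are removed first. For numbered styles a new
#' citation starts at a line whose label is the next consecutive integer;
#' intervening lines are continuation (line-wrapped) text. For author-year
#' sections, blank lines separate entries; absent blank lines, a new entry
#' starts at an unindented surname-comma-initial line.
#'
#' A returned string is correct when it contains the entire reference and
#' nothing that belongs to another citation, a page footer, or body text;
#' its own label and surrounding whitespace are allowed.
#'
#' @param section A `reference_section`.
#' @param style Label style; `NULL` (default) auto-detects via
#'   [detect_label_style()].
#' @param footer_patterns Per-line drop patterns, see
#'   [default_footer_patterns()].
#' @return A data.frame with columns `doc_id`, `index` (1-based, consecutive),
#'   `label` (printed marker, `""` for author-year), `raw` (verbatim lines of
#'   the citation joined with newlines), `start`, `end` (1-based inclusive
#'   offsets into `section$raw_text`). Zero rows for an empty section.
#' @export
segment_references <- function(section, style = NULL,
                               footer_patterns = default_footer_patterns()) {
  stopifnot(inherits(section, "reference_section"))
  if (is.null(style)) style <- detect_label_style(section)
  li <- section_body_lines(section)
  keep <- !is_footer_line(li$line, footer_patterns) & nzchar(trimws(li$line))
  if (style == "author_year") {
    # blank lines are entry separators there, so retain the information
    keep_blank <- !is_footer_line(li$line, footer_patterns)
    li_all <- li[keep_blank, , drop = FALSE]
    groups <- split_author_year(li_all$line)
    li <- li_all
  } else {
    li <- li[keep, , drop = FALSE]
    groups <- split_numbered(li$line, style)
  }
  if (!nrow(li) || !length(groups)) {
    return(empty_citations(section$doc_id))
  }

  pat <- if (style == "author_year") NULL else label_patterns()[[style]]
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    lines <- li$line[idx]
    lines <- lines[nzchar(trimws(lines))]
    raw <- paste(lines, collapse = "\n")
    label <- ""
    if (!is.null(pat)) {
      lm <- stringi::stri_match_first_regex(li$line[idx[1]], pat)
      if (!is.na(lm[1, 1])) label <- trimws(lm[1, 1])
    }
    out[[g]] <- data.frame(doc_id = section$doc_id, index = g, label = label,
                           raw = raw,
                           start = li$start[idx[1]],
                           end = li$end[idx[length(idx)]],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

empty_citations <- function(doc_id) {
  data.frame(doc_id = character(), index = integer(), label = character(),
             raw = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

is_footer_line <- function(lines, patterns) {
  hit <- rep(FALSE, length(lines))
  for (p in patterns) {
    hit <- hit | stringi::stri_detect_regex(lines, p)
  }
  hit
}

# Lines of the section body (heading line excluded), with 1-based inclusive
# offsets into section$raw_text.
section_body_lines <- function(section) {
  txt <- section$raw_text
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (!length(lines)) {
    return(data.frame(line = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  nch <- nchar(lines)
  start <- cumsum(c(1L, nch[-length(nch)] + 1L))
  df <- data.frame(line = lines, start = start, end = start + nch - 1L,
                   stringsAsFactors = FALSE)
  df[-1L, , drop = FALSE]  # first line is the heading
}

# Group body lines into citations for a numeric label style: a new citation
# opens at a line carrying the next consecutive label (1, 2, 3, ...); the
# consecutive requirement keeps wrapped lines that happen to start with a
# number (years, page ranges) from opening spurious entries.
split_numbered <- function(lines, style) {
  pat <- label_patterns()[[style]]
  m <- stringi::stri_match_first_regex(lines, pat)[, 2]
  nums <- suppressWarnings(as.integer(m))
  groups <- list()
  current <- integer()
  expected <- 1L
  for (i in seq_along(lines)) {
    if (!is.na(nums[i]) && nums[i] == expected) {
      if (length(current)) groups[[length(groups) + 1L]] <- current
      current <- i
      expected <- expected + 1L
    } else if (length(current)) {
      current <- c(current, i)
    }
    # lines before label "1" are stray section-head matter; dropped
  }
  if (length(current)) groups[[length(groups) + 1L]] <- current
  groups
}

author_year_start_pattern <- function() {
  # "Surname, A." / "Surname AB," at indent 0; unicode letters allowed
  "^\\p{Lu}[\\p{L}'-]+,?[ \t]+\\p{Lu}"
}

split_author_year <- function(lines) {
  blank <- !nzchar(trimws(lines))
  has_sep <- any(blank)
  groups <- list()
  current <- integer()
  for (i in seq_along(lines)) {
    if (blank[i]) {
      if (length(current)) groups[[length(groups) + 1L]] <- current
      current <- integer()
      next
    }
    new_entry <- if (has_sep) {
      FALSE  # blank lines are authoritative separators
    } else {
      stringi::stri_detect_regex(lines[i], author_year_start_pattern()) &&
        length(current) > 0L
    }
    if (new_entry) {
      groups[[length(groups) + 1L]] <- current
      current <- i
    } else {
      current <- c(current, i)
    }
  }
  if (length(current)) groups[[length(groups) + 1L]] <- current
  groups
}

#' Canonical form of a citation string for comparison
#'
#' Strips a leading numeric label (`[12]`, `12.`, `(12)`) and collapses all
#' whitespace runs to single spaces. Two strings with equal canonical form
#' carry the same reference content; this is the equality used when checking
#' a segmented string against a gold reference.
#'
#' @param raw Character vector of citation strings.
#' @return Character vector of canonical forms.
#' @export
normalize_citation <- function(raw) {
  x <- stringi::stri_replace_first_regex(
    raw, "^[ \t]*(?:\\[\\d+\\]|\\(\\d+\\)|\\d+\\.)[ \t]*", "")
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  trimws(x)
}
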