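#' Specification for a synthetic snowballing corpus
#'
#' The generator emulates the shape of a citation-snowballing study: a
#' bibliographic index, a set of review-style seed articles whose reference
#' lists cite indexed works, excluded citation types (websites, books, grey
#' literature), works cited but absent from the index, page-footer noise and
#' line wraps inside reference lists, citation links between records for
#' recursion, and per-record link behavior (working, broken, dynamic,
#' access-denied, missing).
#'
#' Defaults mirror the composition of a 20-review neuraminidase-inhibitor
#' evaluation corpus: about 53 references per review, roughly 10% excluded
#' citation types, roughly 22% of included citations not indexed, and link
#' behavior dominated by working full-text links with a minority of broken,
#' dynamically generated, or subscription-blocked links.
#'
#' @param n_records Number of records in the bibliographic index.
#' @param n_seed_articles Number of rendered review articles.
#' @param refs_per_article Length-2 integer range (inclusive) of references
#'   per article.
#' @param styles Named weights over citation styles `bracket_number`,
#'   `dot_number`, `author_year`; one style is drawn per article.
#' @param footer_noise_rate Probability of inserting a page-footer line after
#'   each rendered reference.
#' @param excluded_type_rate Share of citations rendered as excluded types
#'   (website/book/grey literature), `included = FALSE` in the gold standard.
#' @param unindexed_rate Share of *included* citations whose work is not in
#'   the index (`indexed = FALSE`).
#' @param link_failure_weights Named weights over planned retrieval outcomes
#'   `full_text`, `abstract_only`, `broken_link`, `no_link`,
#'   `dynamic_link_unresolved`, `access_denied`.
#' @param citation_depth Depth of the citation DAG between index records
#'   (records at level `l < citation_depth` cite records at level `l + 1`).
#' @param doi_rate Fraction of records carrying a DOI.
#' @param wrap_width Column at which reference strings are line-wrapped in
#'   the rendered articles.
#' @param duplicate_title_rate Share of records given a title copied from
#'   another record, to exercise the ambiguous-match path. Default 0:
#'   titles are unique by construction.
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_records = 1000L,
                        n_seed_articles = 20L,
                        refs_per_article = c(45L, 60L),
                        styles = c(bracket_number = 0.4, dot_number = 0.4,
                                   author_year = 0.2),
                        footer_noise_rate = 0.1,
                        excluded_type_rate = 0.10,
                        unindexed_rate = 0.22,
                        link_failure_weights = c(full_text = 0.75,
                                                 abstract_only = 0.02,
                                                 broken_link = 0.10,
                                                 no_link = 0.01,
                                                 dynamic_link_unresolved = 0.09,
                                                 access_denied = 0.03),
                        citation_depth = 2L,
                        doi_rate = 0.6,
                        wrap_width = 80L,
                        duplicate_title_rate = 0,
                        seed = 1L) {
  stopifnot(n_records >= 0L, n_seed_articles >= 0L,
            length(refs_per_article) == 2L,
            refs_per_article[1] <= refs_per_article[2],
            all(c(footer_noise_rate, excluded_type_rate, unindexed_rate,
                  doi_rate, duplicate_title_rate) >= 0),
            all(c(footer_noise_rate, excluded_type_rate, unindexed_rate,
                  doi_rate, duplicate_title_rate) <= 1),
            all(styles >= 0), sum(styles) > 0,
            all(link_failure_weights >= 0), sum(link_failure_weights) > 0,
            citation_depth >= 0L)
  structure(list(n_records = as.integer(n_records),
                 n_seed_articles = as.integer(n_seed_articles),
                 refs_per_article = as.integer(refs_per_article),
                 styles = styles / sum(styles),
                 footer_noise_rate = footer_noise_rate,
                 excluded_type_rate = excluded_type_rate,
                 unindexed_rate = unindexed_rate,
                 link_failure_weights =
                   link_failure_weights / sum(link_failure_weights),
                 citation_depth = as.integer(citation_depth),
                 doi_rate = doi_rate,
                 wrap_width = as.integer(wrap_width),
                 duplicate_title_rate = duplicate_title_rate,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

# scoped RNG: run code under `seed` without disturbing the caller's stream
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

syllables <- function() {
  c("ba", "be", "bi", "bo", "bu", "da", "de", "do", "du", "fa", "fe", "fi",
    "ga", "go", "ka", "ke", "ki", "ko", "la", "le", "li", "lo", "lu", "ma",
    "me", "mi", "mo", "mu", "na", "ne", "ni", "no", "nu", "pa", "pe", "pi",
    "po", "ra", "re", "ri", "ro", "ru", "sa", "se", "si", "so", "su", "ta",
    "te", "ti", "to", "tu", "va", "ve", "vi", "vo", "za", "zo")
}

synth_word <- function(n_syll = 2L) {
  paste(sample(syllables(), n_syll, replace = TRUE), collapse = "")
}

cap <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

synth_title <- function() {
  n <- sample(4:7, 1)
  words <- vapply(seq_len(n), function(i) synth_word(sample(2:3, 1)), "")
  cap(paste(words, collapse = " "))
}

synth_surname <- function() cap(synth_word(sample(2:3, 1)))

synth_initials <- function() {
  paste(sample(LETTERS, sample(1:2, 1), replace = TRUE), collapse = "")
}

synth_venue_pool <- function(n) {
  vapply(seq_len(n), function(i) {
    switch(sample(3, 1),
           paste("Journal of", cap(synth_word(2)), cap(synth_word(2))),
           paste(cap(synth_word(2)), "Review"),
           paste("Annals of", cap(synth_word(3))))
  }, "")
}

#' Generate a synthetic bibliographic index
#'
#' Records get pronounceable titles, authors and venues drawn from syllable
#' tables under the spec's seed; DOIs for a configurable fraction; citation
#' links forming a DAG of the requested depth; and a planned retrieval
#' outcome per record (drawn from `link_failure_weights`) realized through
#' its URL list. The planned outcomes are attached as the `"link_plan"`
#' attribute (generator bookkeeping used to build the fixture store).
#'
#' @param spec A `corpus_spec`.
#' @return A `bib_index` (empty for `n_records = 0`).
#' @export
generate_index <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  if (spec$n_records == 0L) {
    idx <- bib_index(list())
    attr(idx, "link_plan") <- character(0)
    return(idx)
  }
  local_seed(spec$seed, {
    n <- spec$n_records
    venues <- synth_venue_pool(max(5L, n %/% 20L))
    titles <- character(n)
    seen <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
      repeat {
        t <- synth_title()
        if (is.null(seen[[tolower(t)]])) {
          seen[[tolower(t)]] <- TRUE
          titles[i] <- t
          break
        }
      }
    }
    if (spec$duplicate_title_rate > 0 && n > 1L) {
      ndup <- round(spec$duplicate_title_rate * n)
      if (ndup > 0L) {
        dup_to <- sample(n, ndup)
        dup_from <- sample(setdiff(seq_len(n), dup_to), ndup, replace = TRUE)
        titles[dup_to] <- titles[dup_from]
      }
    }

    levels <- sample(0:spec$citation_depth, n, replace = TRUE)
    plan <- sample(names(spec$link_failure_weights), n, replace = TRUE,
                   prob = spec$link_failure_weights)
    records <- vector("list", n)
    for (i in seq_len(n)) {
      id <- sprintf("R%05d", i)
      n_auth <- sample(1:5, 1)
      authors <- vapply(seq_len(n_auth), function(a)
        paste(synth_surname(), synth_initials()), "")
      year <- sample(1985:2014, 1)
      doi <- if (stats::runif(1) < spec$doi_rate)
        sprintf("10.%04d/synth.%05d", 1000L + (i %% 9000L), i) else NA_character_
      cited <- character(0)
      if (levels[i] < spec$citation_depth) {
        pool <- which(levels == levels[i] + 1L)
        if (length(pool)) {
          cited <- sprintf("R%05d",
                           sort(sample(pool, min(length(pool),
                                                 sample(3:8, 1)))))
        }
      }
      records[[i]] <- list(record_id = id, title = titles[i],
                           authors = authors, venue = sample(venues, 1),
                           year = year, doi = doi,
                           urls = plan_urls(id, plan[i]),
                           abstract_ref = NA_character_,
                           fulltext_ref = NA_character_,
                           cited_ids = cited, level = levels[i])
    }
    idx <- bib_index(records)
    names(plan) <- idx$ids
    attr(idx, "link_plan") <- plan
    idx
  })
}

# URL list realizing a planned retrieval outcome
plan_urls <- function(id, plan) {
  ft <- list(url = sprintf("https://synth.example/%s/full", id),
             kind = "fulltext")
  ab <- list(url = sprintf("https://synth.example/%s/abstract", id),
             kind = "abstract")
  switch(plan,
         full_text = list(ft),
         abstract_only = list(ft, ab),  # fulltext link is access-denied
         broken_link = list(ft),
         no_link = list(),
         dynamic_link_unresolved = list(ft),
         access_denied = list(ft))
}

#' Render one bibliographic record as a reference string
#'
#' Deterministic formatting of authors, title, venue, year, volume and pages
#' in the requested citation style.
#'
#' @param record A bibliographic record.
#' @param style `"bracket_number"`, `"dot_number"`, `"paren_number"` or
#'   `"author_year"`.
#' @param k List position, used for the numeric label.
#' @return A single-line reference string.
#' @export
render_citation <- function(record, style = "dot_number", k = 1L) {
  vol <- (record$year %% 30L) + 1L
  p1 <- (nchar(record$title) * 7L) %% 900L + 1L
  p2 <- p1 + (nchar(record$venue) %% 20L) + 4L
  core <- switch(
    style,
    author_year = {
      auth <- paste(vapply(record$authors, function(a) {
        parts <- strsplit(a, " ", fixed = TRUE)[[1]]
        paste0(parts[1], ", ",
               paste0(strsplit(parts[2], "")[[1]], ".", collapse = " "))
      }, ""), collapse = ", ")
      sprintf("%s (%d). %s. %s, %d, %d-%d.", auth, record$year,
              record$title, record$venue, vol, p1, p2)
    },
    sprintf("%s. %s. %s. %d;%d:%d-%d.",
            paste(record$authors, collapse = ", "), record$title,
            record$venue, record$year, vol, p1, p2))
  label <- switch(style,
                  bracket_number = sprintf("[%d] ", k),
                  dot_number = sprintf("%d. ", k),
                  paren_number = sprintf("(%d) ", k),
                  author_year = "")
  paste0(label, core)
}

# excluded citation types: websites, books, grey literature
render_excluded_citation <- function(style, k) {
  kind <- sample(c("website", "book", "grey"), 1)
  core <- switch(kind,
    website = sprintf("%s. Available at: http://%s.example/%s. Accessed %d.",
                      synth_title(), synth_word(3), synth_word(2),
                      sample(2008:2013, 1)),
    book = sprintf("%s %s. %s. %s: %s Press; %d.",
                   synth_surname(), synth_initials(), synth_title(),
                   cap(synth_word(2)), cap(synth_word(2)),
                   sample(1990:2012, 1)),
    grey = sprintf("%s. %s. Technical Report %s-%d; %d.",
                   paste(synth_surname(), synth_initials()), synth_title(),
                   toupper(synth_word(1)), sample(1:99, 1),
                   sample(2000:2013, 1)))
  label <- switch(style,
                  bracket_number = sprintf("[%d] ", k),
                  dot_number = sprintf("%d. ", k),
                  paren_number = sprintf("(%d) ", k),
                  author_year = "")
  if (style == "author_year" && kind == "website") {
    # author-year lists still open entries with a name-like token
    core <- sprintf("%s, %s. (%d). %s", synth_surname(),
                    paste0(sample(LETTERS, 1), "."), sample(2008:2013, 1),
                    core)
  }
  paste0(label, core)
}

synth_footer_line <- function() {
  sprintf("%s | Vol %d | p. %d", cap(synth_word(3)), sample(1:40, 1),
          sample(1:999, 1))
}

synth_paragraph <- function(n_words) {
  words <- vapply(seq_len(n_words), function(i) synth_word(sample(2:3, 1)), "")
  sent_len <- 12L
  idx <- seq(1, length(words), by = sent_len)
  sentences <- vapply(idx, function(s) {
    chunk <- words[s:min(s + sent_len - 1L, length(words))]
    paste0(cap(paste(chunk, collapse = " ")), ".")
  }, "")
  paste(sentences, collapse = " ")
}

#' Generate rendered articles, gold standard and retrieval fixtures
#'
#' Each article is synthetic body text followed by a "References" heading and
#' a rendered reference list in one citation style, with line wraps at the
#' spec's wrap width and page-footer lines interleaved at the footer-noise
#' rate. Body text is padded so the heading always falls after the character
#' midpoint. Excluded citation types are rendered as website/book/grey
#' strings (`included = FALSE`); a configurable share of included citations
#' cite works absent from the index (`indexed = FALSE`). The fixture store
#' realizes every record's planned link behavior; full-text payloads are
#' themselves rendered articles citing the record's `cited_ids`, so the
#' snowballing engine can recurse over them.
#'
#' @param spec A `corpus_spec`.
#' @param index A `bib_index` from [generate_index()].
#' @return List with `articles` (list of rendered articles: `doc_id`, `text`,
#'   `style`, `gold_section_start`, `gold_section_end`, `citations`
#'   data.frame), `gold` (flat gold-standard data.frame, see [read_gold()]),
#'   and `store` (a `fixture_store`).
#' @export
generate_articles <- function(spec, index) {
  stopifnot(inherits(spec, "corpus_spec"), inherits(index, "bib_index"))
  local_seed(spec$seed + 1L, {
    plan <- attr(index, "link_plan")
    levels <- vapply(index$records, function(r) r$level %||% 0L, integer(1))
    seed_pool <- index$ids[levels == 0L]
    if (length(seed_pool) < 2L) seed_pool <- index$ids

    articles <- vector("list", spec$n_seed_articles)
    gold <- list()
    for (j in seq_len(spec$n_seed_articles)) {
      doc_id <- sprintf("A%03d", j)
      style <- sample(names(spec$styles), 1, prob = spec$styles)
      n_refs <- sample(seq(spec$refs_per_article[1],
                           spec$refs_per_article[2]), 1)

      pool <- sample(seed_pool, min(length(seed_pool), n_refs))
      pool_i <- 0L
      cites <- vector("list", n_refs)
      for (k in seq_len(n_refs)) {
        u <- stats::runif(1)
        if (u < spec$excluded_type_rate) {
          cites[[k]] <- list(raw = render_excluded_citation(style, k),
                             true_record_id = NA_character_,
                             included = FALSE, indexed = FALSE)
        } else if (u < spec$excluded_type_rate +
                   (1 - spec$excluded_type_rate) * spec$unindexed_rate ||
                   pool_i >= length(pool)) {
          ghost <- synth_ghost_record()
          cites[[k]] <- list(raw = render_citation(ghost, style, k),
                             true_record_id = NA_character_,
                             included = TRUE, indexed = FALSE)
        } else {
          pool_i <- pool_i + 1L
          rec <- index$records[[pool[pool_i]]]
          cites[[k]] <- list(raw = render_citation(rec, style, k),
                             true_record_id = rec$record_id,
                             included = TRUE, indexed = TRUE)
        }
      }
      art <- assemble_article(doc_id, style, cites, spec)
      articles[[j]] <- art
      gold[[j]] <- data.frame(doc_id = doc_id,
                              index = seq_len(n_refs),
                              true_record_id = vapply(cites, function(x)
                                x$true_record_id, ""),
                              included = vapply(cites, function(x)
                                x$included, TRUE),
                              indexed = vapply(cites, function(x)
                                x$indexed, TRUE),
                              stringsAsFactors = FALSE)
    }
    store <- build_store(spec, index, plan)
    list(articles = articles,
         gold = if (length(gold)) do.call(rbind, gold) else
           data.frame(doc_id = character(), index = integer(),
                      true_record_id = character(), included = logical(),
                      indexed = logical(), stringsAsFactors = FALSE),
         store = store)
  })
}

# a plausible scholarly record that is NOT in the index
synth_ghost_record <- function() {
  list(record_id = NA_character_, title = synth_title(),
       authors = vapply(seq_len(sample(1:4, 1)), function(a)
         paste(synth_surname(), synth_initials()), ""),
       venue = paste("Journal of", cap(synth_word(2)), cap(synth_word(2))),
       year = sample(1985:2014, 1))
}

# body + heading + wrapped reference list (+ footer noise); the body is
# padded past the reference-list length so the heading clears the midpoint
assemble_article <- function(doc_id, style, cites, spec) {
  ref_lines <- character(0)
  for (k in seq_along(cites)) {
    wrapped <- strwrap(cites[[k]]$raw, width = spec$wrap_width)
    ref_lines <- c(ref_lines, wrapped)
    if (style == "author_year" && k < length(cites)) {
      ref_lines <- c(ref_lines, "")
    }
    if (stats::runif(1) < spec$footer_noise_rate) {
      ref_lines <- c(ref_lines, synth_footer_line())
    }
  }
  section_block <- paste(c("References", ref_lines), collapse = "\n")
  # body must outweigh the reference section for the heading to sit past 50%
  target <- nchar(section_block) + 200L
  body <- synth_paragraph(max(60L, ceiling(target / 6)))
  while (nchar(body) < target) {
    body <- paste(body, synth_paragraph(60L))
  }
  text <- paste0(body, "\n\n", section_block)
  gold_start <- nchar(body) + 3L  # heading begins after "\n\n"
  raws <- vapply(cites, function(x) x$raw, "")
  list(doc_id = doc_id, text = text, style = style,
       gold_section_start = gold_start, gold_section_end = nchar(text),
       citations = data.frame(index = seq_along(cites), raw = raws,
                              stringsAsFactors = FALSE))
}

# fixture store realizing each record's planned outcome; full-text payloads
# are rendered articles over the record's cited_ids so recursion works
build_store <- function(spec, index, plan) {
  entries <- list()
  for (id in index$ids) {
    rec <- index$records[[id]]
    p <- plan[[id]]
    if (is.null(p) || p == "no_link") next
    ft_url <- sprintf("https://synth.example/%s/full", id)
    ab_url <- sprintf("https://synth.example/%s/abstract", id)
    if (p == "full_text") {
      entries[[ft_url]] <- list(payload = record_fulltext(rec, index, spec),
                                kind = "fulltext")
    } else if (p == "abstract_only") {
      entries[[ft_url]] <- list(failure = "access_denied")
      entries[[ab_url]] <- list(payload = sprintf("Abstract. %s.", rec$title),
                                kind = "abstract")
    } else if (p == "broken_link") {
      entries[[ft_url]] <- list(failure = "broken_link")
    } else if (p == "dynamic_link_unresolved") {
      entries[[ft_url]] <- list(failure = "dynamic_link_unresolved")
    } else if (p == "access_denied") {
      entries[[ft_url]] <- list(failure = "access_denied")
    }
  }
  fixture_store(entries)
}

record_fulltext <- function(rec, index, spec) {
  cited <- rec$cited_ids
  cites <- lapply(seq_along(cited), function(k) {
    child <- index$records[[cited[k]]]
    list(raw = render_citation(child, "dot_number", k))
  })
  if (!length(cites)) {
    # leaf: body with an empty reference section
    body <- synth_paragraph(80L)
    return(paste0(body, "\n\nReferences\n"))
  }
  assemble_article(rec$record_id, "dot_number", cites,
                   spec_no_noise(spec))$text
}

spec_no_noise <- function(spec) {
  s <- spec
  s$footer_noise_rate <- 0
  s
}

#' Generate a complete synthetic corpus
#'
#' Runs [generate_index()] and [generate_articles()] under the spec's seed.
#' Identical specs (including the seed) produce identical corpora.
#'
#' @param spec A `corpus_spec`.
#' @return An object of class `synthetic_corpus`: list with `spec`, `index`,
#'   `articles`, `gold`, `store`.
#' @export
generate_corpus <- function(spec = corpus_spec()) {
  index <- generate_index(spec)
  arts <- generate_articles(spec, index)
  structure(list(spec = spec, index = index, articles = arts$articles,
                 gold = arts$gold, store = arts$store),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus: %d records, %d articles, %d gold citations, %d store urls>\n",
              x$index$n, length(x$articles), nrow(x$gold),
              length(x$store$entries)))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Emits `index.jsonl`, `articles/<doc_id>.txt`, `gold.jsonl` and `store/`
#' (fixture manifest + payloads).
#'
#' @param corpus A `synthetic_corpus`.
#' @param dir Output directory (created if missing).
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(file.path(dir, "articles"), recursive = TRUE,
             showWarnings = FALSE)
  write_bib_index(corpus$index, file.path(dir, "index.jsonl"))
  for (a in corpus$articles) {
    writeLines(a$text, file.path(dir, "articles", paste0(a$doc_id, ".txt")),
               useBytes = TRUE)
  }
  write_gold(corpus$gold, file.path(dir, "gold.jsonl"))
  write_fixture_store(corpus$store, file.path(dir, "store"))
  invisible(dir)
}

#' Seed documents of a synthetic corpus
#' @param corpus A `synthetic_corpus`.
#' @return List of `source_document`s, one per rendered article.
#' @export
corpus_seed_documents <- function(corpus) {
  lapply(corpus$articles, function(a) normalize_text(a$text, a$doc_id))
}
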