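test_that("generation is fully deterministic under the seed", {
  s <- small_spec(seed = 99)
  c1 <- generate_corpus(s)
  c2 <- generate_corpus(s)
  expect_identical(c1$index$records, c2$index$records)
  expect_identical(c1$gold, c2$gold)
  expect_identical(lapply(c1$articles, `[[`, "text"),
                   lapply(c2$articles, `[[`, "text"))
  expect_identical(c1$store$entries, c2$store$entries)
  # a different seed moves the corpus
  c3 <- generate_corpus(small_spec(seed = 100))
  expect_false(identical(c1$gold, c3$gold))
})

test_that("an empty spec yields an empty index", {
  idx <- generate_index(corpus_spec(n_records = 0, n_seed_articles = 0))
  expect_equal(idx$n, 0L)
})

test_that("record fields satisfy the index invariants", {
  corpus <- cached_corpus("small", small_spec())
  years <- vapply(corpus$index$records, `[[`, 0L, "year")
  expect_true(all(years >= 1800 & years <= 2100))
  expect_false(anyDuplicated(corpus$index$ids) > 0)
  titles <- vapply(corpus$index$records, `[[`, "", "title")
  expect_false(anyDuplicated(tolower(titles)) > 0)  # unique by construction
  # cited ids point into the index (DAG over levels)
  for (r in corpus$index$records) {
    expect_true(all(r$cited_ids %in% corpus$index$ids))
  }
})

test_that("composition rates land inside binomial 99% bounds", {
  spec <- corpus_spec(n_records = 400, n_seed_articles = 25,
                      refs_per_article = c(35, 45), seed = 5)
  corpus <- generate_corpus(spec)
  n <- nrow(corpus$gold)
  expect_gt(n, 800)

  # share of excluded citation types around 10%
  n_excl <- sum(!corpus$gold$included)
  bounds <- stats::qbinom(c(0.005, 0.995), n, spec$excluded_type_rate)
  expect_gte(n_excl, bounds[1])
  expect_lte(n_excl, bounds[2])

  # among included citations, the indexed share mirrors 1 - unindexed_rate
  inc <- corpus$gold[corpus$gold$included, ]
  bounds2 <- stats::qbinom(c(0.005, 0.995), nrow(inc),
                           1 - spec$unindexed_rate)
  expect_gte(sum(inc$indexed), bounds2[1])
  expect_lte(sum(inc$indexed), bounds2[2])
})

test_that("gold annotations are internally consistent", {
  corpus <- cached_corpus("small", small_spec())
  g <- corpus$gold
  # indexed implies included; true record implies indexed and in the index
  expect_true(all(g$included[g$indexed]))
  expect_true(all(g$indexed[!is.na(g$true_record_id)]))
  expect_true(all(stats::na.omit(g$true_record_id) %in% corpus$index$ids))
  # every article's heading sits past the midpoint, by construction
  for (a in corpus$articles) {
    expect_no_error(locate_reference_section(normalize_text(a$text, a$doc_id)))
  }
})

test_that("rendered citation styles carry the promised markers", {
  rec <- make_record("R1", "Quantum flux modulation analysis")
  expect_match(render_citation(rec, "bracket_number", 7), "^\\[7\\] ")
  expect_match(render_citation(rec, "dot_number", 7), "^7\\. ")
  expect_match(render_citation(rec, "paren_number", 7), "^\\(7\\) ")
  ay <- render_citation(rec, "author_year", 7)
  expect_match(ay, "^Tester, A\\. B\\. \\(2005\\)\\.")
  # deterministic: same record, same string
  expect_identical(render_citation(rec, "dot_number", 7),
                   render_citation(rec, "dot_number", 7))
})

test_that("render -> segment -> query -> search round-trips to the source record", {
  corpus <- cached_corpus("small", small_spec())
  backend <- local_backend(corpus$index)
  ids <- utils::head(corpus$index$ids, 25)
  for (style in c("bracket_number", "dot_number", "author_year")) {
    for (id in utils::head(ids, 8)) {
      raw <- render_citation(corpus$index$records[[id]], style, 1)
      cand <- search_candidates(build_query(raw), backend, 5)
      expect_equal(cand$record_id[1], id)
    }
  }
})

test_that("zero footer noise lets the segmenter recover every gold citation", {
  corpus <- generate_corpus(small_spec(seed = 13, footer_noise_rate = 0))
  sr <- segmentation_recall(corpus)
  expect_equal(sr$recall, 1.0)
  expect_equal(sr$n_correct, nrow(corpus$gold))
})

test_that("a corpus writes to disk and reads back equivalently", {
  corpus <- generate_corpus(corpus_spec(n_records = 40, n_seed_articles = 2,
                                        refs_per_article = c(4, 6), seed = 3))
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)
  idx <- read_bib_index(file.path(dir, "index.jsonl"))
  expect_equal(idx$ids, corpus$index$ids)
  gold <- read_gold(file.path(dir, "gold.jsonl"))
  expect_equal(gold, corpus$gold)
  store <- read_fixture_store(file.path(dir, "store"))
  expect_setequal(names(store$entries), names(corpus$store$entries))
  art <- read_document(file.path(dir, "articles", "A001.txt"))
  expect_no_error(locate_reference_section(art))
})

test_that("the duplicate-title switch exercises the ambiguous path", {
  spec <- corpus_spec(n_records = 60, n_seed_articles = 1,
                      refs_per_article = c(3, 4),
                      duplicate_title_rate = 0.5, seed = 17)
  index <- generate_index(spec)
  titles <- vapply(index$records, `[[`, "", "title")
  dup <- titles[duplicated(titles)][1]
  expect_false(is.na(dup))
  ids <- index$ids[titles == dup]
  # same-title records tie; the decision must be ambiguous, not a match
  q <- build_query(paste0(dup, "."))
  cand <- search_candidates(q, local_backend(index), 5)
  dec <- decide_match(cand)
  expect_true(dec$status %in% c("ambiguous", "below_threshold"))
})
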