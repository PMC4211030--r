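make_query <- function(tokens) {
  structure(list(doc_id = "d", index = 1L, tokens = tokens),
            class = "search_query")
}

test_that("candidate scoring is weighted token overlap in [0, 1]", {
  rec <- make_record("R1", "quantum flux modulation dynamics")
  expect_equal(score_candidate(c("quantum", "flux"), rec), 1.0)
  expect_equal(score_candidate(c("zzzz", "yyyy"), rec), 0.0)
  # half of equally-weighted tokens present
  expect_equal(score_candidate(c("quantum", "flux", "zzzz", "yyyy"), rec), 0.5)
  # monotone: adding a matched token never lowers the score
  s1 <- score_candidate(c("quantum", "zzzz", "yyyy"), rec)
  s2 <- score_candidate(c("quantum", "flux", "zzzz", "yyyy"), rec)
  expect_gte(s2, s1)
})

test_that("a full-title query ranks its record first in a 100-record index", {
  titles <- handmade_titles(100)
  index <- bib_index(lapply(seq_len(100), function(i)
    make_record(sprintf("R%03d", i), titles[i])))
  backend <- local_backend(index)
  for (i in c(1, 37, 100)) {
    q <- build_query(paste0(titles[i], "."))
    cand <- search_candidates(q, backend, k = 5)
    expect_equal(cand$record_id[1], sprintf("R%03d", i))
    # oracle: exhaustive scoring over every record with the same weights
    w <- idf_weights(index, q$tokens)
    brute <- vapply(index$records, function(r)
      score_candidate(q$tokens, r, w), numeric(1))
    expect_equal(cand$score[1], max(brute))
    expect_equal(cand$record_id[1],
                 index$ids[order(-brute, index$ids)][1])
  }
})

test_that("a query matching nothing returns no candidates", {
  index <- bib_index(list(make_record("R1", "quantum flux modulation")))
  cand <- search_candidates(make_query(c("unrelated", "words")),
                            local_backend(index), 5)
  expect_equal(nrow(cand), 0L)
})

test_that("identical-title records tie and are ordered by record id", {
  index <- bib_index(list(make_record("R2", "quantum flux modulation"),
                          make_record("R1", "quantum flux modulation")))
  cand <- search_candidates(make_query(c("quantum", "flux", "modulation")),
                            local_backend(index), 5)
  expect_equal(cand$record_id, c("R1", "R2"))
  expect_equal(cand$score[1], cand$score[2])
})

test_that("match acceptance follows the threshold-and-margin rule", {
  cand <- function(scores) data.frame(
    record_id = sprintf("R%d", seq_along(scores)), score = scores,
    stringsAsFactors = FALSE)

  expect_equal(decide_match(cand(numeric(0)))$status, "no_candidates")
  d <- decide_match(cand(c(1.0, 0.4)))
  expect_equal(d$status, "matched")
  expect_equal(d$matched_id, "R1")
  expect_equal(d$margin, 0.6)
  # margin 0.02 below delta = 0.05
  expect_equal(decide_match(cand(c(0.72, 0.70)))$status, "ambiguous")
  expect_equal(decide_match(cand(c(0.69)))$status, "below_threshold")
  # a lone candidate has no runner-up to beat
  expect_equal(decide_match(cand(c(0.71)))$status, "matched")
  expect_true(is.na(decide_match(cand(numeric(0)))$matched_id))
})

test_that("backend failures carry the citation reference and are catchable", {
  bad <- http_backend()  # no request function configured
  err <- tryCatch(search_candidates(make_query("token"), bad),
                  citesnow_backend = function(e) e)
  expect_s3_class(err, "citesnow_backend")
  expect_equal(err$doc_id, "d")
})

test_that("records deduplicate by case-folded DOI, else by title and year", {
  a <- make_record("R1", "Quantum Flux", doi = "10.1/AB.C")
  b <- make_record("R2", "Different Title", doi = "10.1/ab.c")
  expect_equal(record_dedup_key(a), record_dedup_key(b))
  c1 <- make_record("R3", "Quantum  Flux!", year = 2005)
  c2 <- make_record("R4", "quantum flux", year = 2005)
  c3 <- make_record("R5", "quantum flux", year = 2006)
  expect_equal(record_dedup_key(c1), record_dedup_key(c2))
  expect_false(record_dedup_key(c2) == record_dedup_key(c3))
})

test_that("index round-trips through JSON lines and validates invariants", {
  corpus <- cached_corpus("small", small_spec())
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_bib_index(corpus$index, path)
  back <- read_bib_index(path)
  expect_equal(back$ids, corpus$index$ids)
  r0 <- corpus$index$records[[5]]
  r1 <- back$records[[5]]
  expect_equal(r1$title, r0$title)
  expect_equal(r1$cited_ids, r0$cited_ids)
  expect_equal(length(r1$urls), length(r0$urls))

  expect_error(bib_index(list(make_record("R1", "t"), make_record("R1", "t"))),
               class = "citesnow_invalid_index")
  expect_error(bib_index(list(make_record("R1", "t", year = 1750))),
               class = "citesnow_invalid_index")
  expect_error(bib_index(list(make_record("R1", "t", doi = "10.1/x"),
                              make_record("R2", "u", doi = "10.1/X"))),
               class = "citesnow_invalid_index")
})

test_that("matched records export to RIS and BibTeX", {
  recs <- list(make_record("R1", "Quantum flux modulation", doi = "10.1/a"))
  ris <- withr::local_tempfile(fileext = ".ris")
  bib <- withr::local_tempfile(fileext = ".bib")
  write_ris(recs, ris)
  write_bibtex(recs, bib)
  ris_txt <- readLines(ris)
  expect_true("TY  - JOUR" %in% ris_txt)
  expect_true("TI  - Quantum flux modulation" %in% ris_txt)
  expect_true(any(grepl("ER  -", ris_txt)))
  bib_txt <- readLines(bib)
  expect_true(any(grepl("^@article\\{R1,", bib_txt)))
  expect_true(any(grepl("doi = \\{10.1/a\\}", bib_txt)))
})
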