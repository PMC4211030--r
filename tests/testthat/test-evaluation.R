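test_that("precision, recall and F1 follow the standard formulas", {
  expect_equal(precision(0, 0), 0)
  expect_equal(precision(5, 5), 0.5)
  expect_equal(recall(0, 10), 0)
  expect_equal(recall(7, 0), 1)
  expect_equal(f1(0, 0), 0)
  for (x in c(0.25, 0.5, 0.921)) expect_equal(f1(x, x), x)
  # harmonic mean is below the arithmetic mean for unequal arguments
  expect_lt(f1(0.9, 0.5), 0.7)
})

test_that("the formulas reproduce the published corpus metrics", {
  # 633 of 949 included citations resolved; 633 of 740 indexed ones
  expect_equal(round(recall(633, 949 - 633), 3), 0.667)
  expect_equal(round(recall(633, 740 - 633), 3), 0.855)
  expect_equal(round(100 * recall(633, 949 - 633), 1), 66.7)
  expect_equal(round(100 * recall(633, 740 - 633), 1), 85.5)
  # F1 per denominator from the printed precision/recall pairs
  expect_equal(round(f1(0.977, 0.600), 3), 0.743)
  expect_equal(round(f1(0.977, 0.667), 3), 0.793)
  expect_equal(round(f1(0.977, 0.855), 3), 0.912)
  expect_equal(round(f1(0.921, 0.483), 3), 0.634)
  expect_equal(round(f1(0.921, 0.540), 3), 0.681)
  expect_equal(round(f1(0.921, 0.702), 3), 0.797)
  expect_equal(round(f1(0.919, 0.475), 3), 0.626)
  expect_equal(round(f1(0.919, 0.696), 3), 0.792)
  expect_equal(round(f1(0.921, 0.829), 3), 0.873)
})

# tiny hand-built run: 4 citations, 3 matched (2 wrong), varied outcomes
tiny_run <- function() {
  gold <- data.frame(doc_id = "d", index = 1:4,
                     true_record_id = c("R1", "R2", NA, NA),
                     included = c(TRUE, TRUE, TRUE, FALSE),
                     indexed = c(TRUE, TRUE, FALSE, FALSE),
                     stringsAsFactors = FALSE)
  decisions <- data.frame(doc_id = "d", index = 1:3,
                          matched_id = c("R1", "R9", "R3"),
                          score = 1, margin = 1, status = "matched",
                          stringsAsFactors = FALSE)
  outcomes <- data.frame(record_id = c("R1", "R9"),
                         outcome = c("full_text", "abstract_only"),
                         stringsAsFactors = FALSE)
  list(gold = gold, decisions = decisions, outcomes = outcomes)
}

test_that("evaluate_run counts confusion cells per stage and denominator", {
  r <- tiny_run()
  rep <- evaluate_run(r$decisions, r$outcomes, r$gold)
  expect_s3_class(rep, "evaluation_report")
  expect_equal(nrow(rep), 9L)

  # only citation 1 is matched to its annotated record
  cit_all <- rep[rep$stage == "citations_retrieved" &
                   rep$denominator == "all", ]
  expect_equal(cit_all$tp, 1L)
  expect_equal(cit_all$fp, 2L)
  expect_equal(cit_all$fn, 3L)
  expect_equal(cit_all$precision, 1 / 3)

  # indexed denominator keeps citations 1-2 only: one correct, one wrong
  cit_idx <- rep[rep$stage == "citations_retrieved" &
                   rep$denominator == "indexed", ]
  expect_equal(cit_idx$tp, 1L)
  expect_equal(cit_idx$fp, 1L)
  expect_equal(cit_idx$n_gold, 2L)

  # abstract stage: R1 (correct) and R9 (wrong match) were fetched
  ab_all <- rep[rep$stage == "abstracts_fetched" & rep$denominator == "all", ]
  expect_equal(ab_all$tp, 1L)
  expect_equal(ab_all$fp, 1L)

  # full text fetched only for the correctly matched R1
  ft_all <- rep[rep$stage == "fulltext_fetched" & rep$denominator == "all", ]
  expect_equal(ft_all$tp, 1L)
  expect_equal(ft_all$fp, 0L)
})

test_that("a perfect run scores 1.0 everywhere", {
  gold <- data.frame(doc_id = "d", index = 1:3,
                     true_record_id = c("R1", "R2", "R3"),
                     included = TRUE, indexed = TRUE,
                     stringsAsFactors = FALSE)
  decisions <- data.frame(doc_id = "d", index = 1:3,
                          matched_id = c("R1", "R2", "R3"),
                          score = 1, margin = 1, status = "matched",
                          stringsAsFactors = FALSE)
  outcomes <- data.frame(record_id = c("R1", "R2", "R3"),
                         outcome = "full_text", stringsAsFactors = FALSE)
  rep <- evaluate_run(decisions, outcomes, gold)
  expect_true(all(rep$precision == 1))
  expect_true(all(rep$recall == 1))
  expect_true(all(rep$f1 == 1))
})

test_that("one wrong match among n correct gives citation precision n/(n+1)", {
  n <- 7L
  gold <- data.frame(doc_id = "d", index = 1:(n + 1),
                     true_record_id = sprintf("R%d", 1:(n + 1)),
                     included = TRUE, indexed = TRUE,
                     stringsAsFactors = FALSE)
  decisions <- data.frame(doc_id = "d", index = 1:(n + 1),
                          matched_id = c(sprintf("R%d", 1:n), "WRONG"),
                          score = 1, margin = 1, status = "matched",
                          stringsAsFactors = FALSE)
  rep <- evaluate_run(decisions,
                      data.frame(record_id = character(),
                                 outcome = character(),
                                 stringsAsFactors = FALSE), gold)
  cit <- rep[rep$stage == "citations_retrieved" & rep$denominator == "all", ]
  expect_equal(cit$precision, n / (n + 1))
})

test_that("a gold gap names the offending citation", {
  r <- tiny_run()
  expect_error(evaluate_run(r$decisions, r$outcomes, r$gold[-2, ]),
               regexp = "d#2", class = "citesnow_missing_annotation")
})

test_that("reports print and serialize in the three-by-three layout", {
  r <- tiny_run()
  rep <- evaluate_run(r$decisions, r$outcomes, r$gold)
  expect_output(print(rep), "citations_retrieved")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_report_tsv(rep, tsv)
  lines <- readLines(tsv)
  expect_length(lines, 1 + 3 * 4)  # header + 3 stage blocks of 4 lines
  expect_match(lines[1], "all_n4\tincluded_n3\tindexed_n2")
  expect_match(lines[3], "^precision\t")
})
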