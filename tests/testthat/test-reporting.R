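ct <- table2_fixture()

published_report <- function() {
  develop_models(ct, c("decline10", "decline20"),
                 list(decline10 = fix10_subset, decline20 = fix20_subset))
}

test_that("text reports state both solution paths and the partitions", {
  txt <- render_report(published_report(), "text")
  expect_match(txt, "DON_TURNOVER", fixed = TRUE)
  expect_match(txt, "not LOW_BASELINE AND SUPPORT; OR DON_TURNOVER",
               fixed = TRUE)
  expect_match(txt, "consistency 13/13 = 100%; coverage 13/15 = 87%",
               fixed = TRUE)
  expect_match(txt, "consistency 11/11 = 100%; coverage 11/13 = 85%",
               fixed = TRUE)
  expect_match(txt, "4 / 5 / 4 with 2 uncovered", fixed = TRUE)
  expect_match(txt, "6 / 3 / 2 with 2 uncovered", fixed = TRUE)
})

test_that("reports without a qualifying model state the floor and reasons", {
  df <- data.frame(case_id = letters[1:5], x = c(1, 1, 1, 0, 0),
                   out = c(1, 1, 0, 0, 0))
  t2 <- case_table(df, c(x = "crisp"), "out", "case_id")
  rep <- develop_models(t2, "out", "x",
                        criteria = selection_criteria(min_consistency = 0.9))
  expect_false(rep$qualifies)
  txt <- render_report(rep, "text")
  expect_match(txt, "no qualifying model down to threshold 0.65", fixed = TRUE)
  expect_match(txt, "no output-1 truth-table row", fixed = TRUE)
  expect_match(txt, "consistency 0.67 below 0.90", fixed = TRUE)
})

test_that("JSON reports round-trip every count and term exactly", {
  rep <- published_report()
  parsed <- jsonlite::fromJSON(render_report(rep, "json"),
                               simplifyVector = FALSE)
  expect_true(parsed$qualifies)
  o10 <- parsed$outcomes$decline10
  expect_equal(o10$metrics$n_covered_positive, 13)
  expect_equal(o10$metrics$n_outcome, 15)
  expect_equal(o10$partition$uncovered, 2)
  expect_equal(vapply(o10$partition$paths, `[[`, 0L, "n_exclusive"),
               c(4L, 5L))
  terms <- lapply(o10$model$terms, function(tm) {
    lits <- vapply(tm, function(l) paste0(l$factor, "=", l$value), "")
    sort(lits)
  })
  expect_setequal(vapply(terms, paste, "", collapse = "&"),
                  c("don_turnover=1", "low_baseline=0&support=1"))
  o20 <- parsed$outcomes$decline20
  expect_equal(o20$metrics$n_covered_positive, 11)
  expect_equal(vapply(o20$partition$paths, `[[`, 0L, "n_exclusive"),
               c(6L, 3L))
  # round-trip of the exact consistency/coverage fractions
  expect_equal(o10$metrics$coverage, 13 / 15)
  expect_equal(o20$metrics$coverage, 11 / 13)
})

test_that("unknown formats are a usage error", {
  expect_error(render_report(published_report(), "pdf"),
               class = "csqca_usage_error")
  expect_error(render_report(list(), "text"), class = "csqca_usage_error")
})
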