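test_that("the packaged facility table loads with its declared structure", {
  ct <- optimistic_facilities()
  expect_s3_class(ct, "case_table")
  expect_equal(n_cases(ct), 19)
  expect_equal(ct$case_ids, as.character(1:19))
  kinds <- vapply(ct$factors, `[[`, "", "kind")
  expect_equal(sum(kinds == "crisp"), 4)
  expect_equal(ct$outcomes, c("decline10", "decline20"))
  # case order preserved from file
  expect_equal(ct$data$pre_rate[1], 3.146)
})

test_that("a header-only file yields a valid empty table", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("case_id,x,out", f)
  ct <- load_case_table(f, list(id = "case_id",
                                factors = list(x = list(kind = "crisp")),
                                outcomes = "out"))
  expect_equal(n_cases(ct), 0)
  expect_error(consistency(conjunction(x = 1), ct, "out"),
               class = "csqca_undefined_metric_error")
})

test_that("schema violations are rejected with named classes", {
  base <- data.frame(case_id = c("a", "b"), x = c(1, 0), out = c(1, 0))
  decls <- list(factor_decl("x"))

  bad <- base; bad$x[2] <- 2
  expect_error(case_table(bad, decls, "out", "case_id"),
               class = "csqca_schema_error")

  bad <- base; bad$x[1] <- NA
  expect_error(case_table(bad, decls, "out", "case_id"),
               class = "csqca_schema_error")

  bad <- base; bad$case_id <- c("a", "a")
  expect_error(case_table(bad, decls, "out", "case_id"),
               regexp = "duplicate case id", class = "csqca_schema_error")

  expect_error(case_table(base, list(factor_decl("missing_col")), "out",
                          "case_id"),
               regexp = "missing column", class = "csqca_schema_error")

  mv <- base; mv$m <- c("hi", "nope")
  expect_error(
    case_table(mv, c(decls, list(factor_decl("m", "multivalue",
                                             levels = c("hi", "lo")))),
               "out", "case_id"),
    regexp = "declared levels", class = "csqca_schema_error")
})

test_that("case tables round-trip through CSV", {
  ct <- optimistic_facilities()
  f <- withr::local_tempfile(fileext = ".csv")
  write_case_table(ct, f, id_col = "facility_id")
  back <- load_case_table(
    f, system.file("extdata", "optimistic_schema.json", package = "csqca"))
  expect_equal(back$data, ct$data)
  expect_equal(back$case_ids, ct$case_ids)
})

test_that("recomputed decline outcomes reproduce the printed outcome columns", {
  ct <- optimistic_facilities()
  oc <- derive_decline_outcomes(ct$data$pre_rate, ct$data$during_rate,
                                c(0.10, 0.20))
  expect_equal(oc$decline10, ct$data$decline10)
  expect_equal(oc$decline20, ct$data$decline20)
})

test_that("decline comparison is inclusive and handles edge rates", {
  # facility 1: large decline; 14: ~13.8%; 16: rate increased
  oc <- derive_decline_outcomes(c(3.146, 1.331, 0.963),
                                c(1.251, 1.147, 1.137), c(0.10, 0.20))
  expect_equal(oc$decline10, c(1L, 1L, 0L))
  expect_equal(oc$decline20, c(1L, 0L, 0L))
  # exactly at the threshold counts as achieved
  expect_equal(derive_decline_outcomes(1, 0.9, 0.10)[[1]], 1L)
  # no decline fails every positive threshold
  expect_equal(unlist(derive_decline_outcomes(2, 2, c(0.1, 0.2))),
               c(decline10 = 0L, decline20 = 0L))
  expect_error(derive_decline_outcomes(0, 1, 0.1), class = "csqca_rate_error")
  expect_error(derive_decline_outcomes(1, -1, 0.1), class = "csqca_rate_error")
})

test_that("raising the decline threshold never turns a 0 into a 1", {
  set.seed(41)
  for (i in 1:20) {
    pre <- stats::runif(15, 0.2, 5)
    during <- stats::runif(15, 0, 5)
    thr <- sort(stats::runif(3, 0.05, 0.9))
    oc <- derive_decline_outcomes(pre, during, thr)
    expect_true(all(oc[[2]] <= oc[[1]]))
    expect_true(all(oc[[3]] <= oc[[2]]))
  }
})

test_that("quantile dichotomization reproduces the baseline-quartile column", {
  ct <- optimistic_facilities()
  g <- dichotomize_by_quantile(ct$data$pre_rate, q = 0.25, direction = "low")
  expect_equal(g, ct$data$low_baseline)
  expect_equal(ct$case_ids[g == 1], c("9", "14", "16", "17", "18"))
})

test_that("quantile cutoff interpolates at rank (n-1)q + 1", {
  # h = 1.75 so the cutoff is 1.75; only the value 1 falls at or below it
  expect_equal(dichotomize_by_quantile(c(1, 2, 3, 4), 0.25, "low"),
               c(1L, 0L, 0L, 0L))
  expect_error(dichotomize_by_quantile(rep(2, 5), 0.25),
               class = "csqca_degenerate_error")
})

test_that("low and high directions are complementary off the cutoff", {
  set.seed(7)
  for (i in 1:10) {
    x <- stats::rnorm(17)
    lo <- dichotomize_by_quantile(x, 0.3, "low")
    hi <- dichotomize_by_quantile(x, 0.3, "high")
    expect_equal(lo + hi, rep(1L, 17))
  }
})

test_that("ordinal dichotomization codes by positive level membership", {
  lv <- c("strongly agree", "agree", "neutral", "disagree")
  pos <- c("agree", "strongly agree")
  expect_equal(dichotomize_ordinal(c("agree", "neutral"), pos, lv), c(1L, 0L))
  expect_equal(dichotomize_ordinal(lv, lv, lv), rep(1L, 4))
  expect_error(dichotomize_ordinal("meh", pos, lv),
               class = "csqca_schema_error")
  expect_error(dichotomize_ordinal("agree", c("agree", "other"), lv),
               class = "csqca_schema_error")
})
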