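ct <- table2_fixture()

test_that("fixture msc settles at cutoff 1.0 with the expected configurations", {
  msc <- enumerate_msc(ct, "decline10", max_order = 4)
  expect_equal(attr(msc, "threshold"), 1)
  expect_equal(msc$formula[1], "don_turnover")
  expect_equal(msc$consistency[1], 1)
  expect_equal(msc$coverage[1], 9 / 15)
  i <- which(msc$formula == "~low_baseline*support")
  expect_length(i, 1)
  expect_equal(msc$coverage[i], 8 / 15)
  # non-minimal supersets of a qualifying condition are excluded
  expect_false(any(grepl("don_turnover\\*", msc$formula) |
                     grepl("\\*don_turnover", msc$formula)))
})

test_that("ranking is by coverage, then order, then formula", {
  msc <- enumerate_msc(ct, "decline10")
  expect_true(all(diff(msc$coverage) <= 1e-12))
  ties <- split(seq_len(nrow(msc)), msc$coverage)
  for (idx in ties) {
    if (length(idx) > 1) expect_true(all(diff(msc$order[sort(idx)]) >= 0))
  }
})

test_that("an all-negative outcome yields an empty result at the floor", {
  df <- data.frame(case_id = letters[1:4], x = c(0, 1, 0, 1), out = 0)
  t2 <- case_table(df, c(x = "crisp"), "out", "case_id")
  msc <- enumerate_msc(t2, "out", max_order = 1, floor = 0.8)
  expect_equal(nrow(msc), 0)
  expect_equal(attr(msc, "threshold"), 0.8)
})

test_that("the cutoff steps down in 5% decrements until conditions qualify", {
  # single factor whose best consistency is 2/3: schedule must stop at 0.65
  df <- data.frame(case_id = letters[1:6], x = c(1, 1, 1, 0, 0, 0),
                   out = c(1, 1, 0, 0, 0, 1))
  t2 <- case_table(df, c(x = "crisp"), "out", "case_id")
  msc <- enumerate_msc(t2, "out", max_order = 1)
  expect_equal(attr(msc, "threshold"), 0.65)
  expect_equal(msc$formula, "x")
})

test_that("multivalue factors contribute one literal per level", {
  df <- data.frame(case_id = letters[1:6],
                   m = c("a", "a", "b", "b", "c", "c"),
                   out = c(1, 1, 0, 0, 0, 0))
  t2 <- case_table(df, list(factor_decl("m", "multivalue",
                                        levels = c("a", "b", "c"))),
                   "out", "case_id")
  msc <- enumerate_msc(t2, "out", max_order = 1)
  expect_equal(msc$formula, "m=a")
  expect_equal(msc$consistency, 1)
  expect_equal(msc$coverage, 1)
})

test_that("msc enumeration agrees with the brute-force oracle", {
  set.seed(97)
  for (i in 1:25) {
    n_fac <- sample(2:6, 1)
    n <- sample(5:25, 1)
    ord <- sample(1:3, 1)
    tab <- random_crisp_table(n, n_fac, p_outcome = stats::runif(1, 0.2, 0.8))
    msc <- enumerate_msc(tab, "Y", max_order = ord)
    orc <- oracle_msc(cbind(tab$data), sprintf("F%d", seq_len(n_fac)), "Y",
                      ord)
    expect_equal(attr(msc, "threshold"), orc$threshold)
    expect_setequal(msc_result_keys(msc), orc$rows$key)
    # consistency/coverage agree per configuration
    if (nrow(msc)) {
      keys <- msc_result_keys(msc)
      o <- orc$rows[match(keys, orc$rows$key), ]
      expect_equal(msc$consistency, o$cons)
      expect_equal(msc$coverage, o$cov)
    }
  }
})
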