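planted <- dnf_model(list(conjunction(A = 1),
                          conjunction(B = 1, C = 0)))

test_that("generator specs validate the planted model and noise structure", {
  spec <- generator_spec(planted, seed = 1)
  expect_equal(spec$planted_factors, c("A", "B", "C"))
  expect_equal(spec$n_noise_binary, 3)       # tops dichotomous factors to six
  expect_equal(spec$n_noise_multivalue, 5)
  expect_error(generator_spec(planted, outcome_flip_prob = 0.5),
               class = "csqca_spec_error")
  taut <- dnf_model(list(conjunction(A = 1), conjunction(A = 0)))
  expect_error(generator_spec(taut), class = "csqca_spec_error")
  expect_error(generator_spec(planted, config_sampling = "weighted"),
               class = "csqca_spec_error")
})

test_that("generation is deterministic in the seed and shaped as declared", {
  spec <- generator_spec(planted, n_cases = 19, seed = 7)
  g1 <- generate_case_table(spec)
  g2 <- generate_case_table(spec)
  expect_identical(g1$table$data, g2$table$data)
  expect_equal(n_cases(g1$table), 19)
  kinds <- vapply(g1$table$factors, `[[`, "", "kind")
  expect_equal(sum(kinds == "crisp"), 6)     # 3 planted + 3 binary noise
  expect_equal(sum(kinds == "multivalue"), 5)
  g3 <- generate_case_table(spec, seed = 8)
  expect_false(identical(g1$table$data, g3$table$data))
})

test_that("without flips every outcome equals the planted-model evaluation", {
  spec <- generator_spec(planted, n_cases = 40,
                         config_sampling = "balanced", seed = 3)
  g <- generate_case_table(spec)
  y <- g$table$data$improved
  expect_equal(y, g$truth$y_true)
  for (i in seq_len(40)) {
    conf <- g$table$data[i, c("A", "B", "C")]
    expect_equal(y[i] == 1L, oracle_eval_model(planted, conf))
  }
  # balanced sampling observed every configuration
  expect_equal(nrow(unique(g$table$data[, c("A", "B", "C")])), 8)
})

test_that("rate emission encodes the outcome in the decline fraction", {
  spec <- generator_spec(planted, n_cases = 30, config_sampling = "balanced",
                         rate_emission = list(threshold = 0.10), seed = 11)
  g <- generate_case_table(spec)
  expect_false("improved" %in% names(g$table$data))
  expect_true(all(g$table$data$pre_rate > 0))
  expect_true(all(g$table$data$during_rate >= 0))
  oc <- derive_decline_outcomes(g$table$data$pre_rate,
                                g$table$data$during_rate, 0.10,
                                names = "improved")
  expect_equal(oc$improved, g$truth$y_true)
})

test_that("noiseless full-coverage replicates recover the planted model exactly", {
  spec <- generator_spec(planted, n_cases = 24,
                         config_sampling = "balanced", seed = 100)
  res <- recovery_experiment(spec, n_reps = 5)
  expect_equal(res$recovery_rate, 1)
  expect_true(all(res$replicates$threshold == 1))
  expect_true(all(res$replicates$term_precision == 1))
  expect_true(all(res$replicates$term_recall == 1))
})

test_that("under-sampled planted configurations break conservative recovery", {
  simple <- dnf_model(list(conjunction(A = 1), conjunction(B = 1)))
  # never observe (A=1, B=0): the A-path's evidence is remainder-dependent
  w <- c(1, 0, 1, 1)   # grid order (A,B): (0,0), (1,0), (0,1), (1,1)
  spec <- generator_spec(simple, n_cases = 30, config_sampling = "weighted",
                         config_weights = w, seed = 5)
  cons <- recovery_experiment(spec, n_reps = 10, strategy = "conservative")
  expect_lt(cons$recovery_rate, 1)
})

test_that("exact-recovery rate does not increase with flip noise", {
  rates <- vapply(c(0, 0.1, 0.2), function(eps) {
    spec <- generator_spec(planted, n_cases = 24,
                           config_sampling = "balanced",
                           outcome_flip_prob = eps, seed = 500)
    recovery_experiment(spec, n_reps = 40)$recovery_rate
  }, 0)
  slack <- 2 * sqrt(0.25 / 40)
  expect_gte(rates[1] + slack, rates[2])
  expect_gte(rates[2] + slack, rates[3])
  expect_equal(rates[1], 1)
})

test_that("heavy flip noise drags the single-condition msc cutoff below 100%", {
  # with 40% outcome flips no single condition (satisfied by ~half the 19
  # cases) stays perfectly consistent, so the schedule must step down
  spec <- generator_spec(planted, n_cases = 19,
                         config_sampling = "balanced",
                         outcome_flip_prob = 0.4, seed = 900)
  below <- vapply(1:30, function(i) {
    g <- generate_case_table(spec, seed = 900 + i)
    m <- enumerate_msc(g$table, "improved", max_order = 1,
                       factors = c("A", "B", "C"))
    attr(m, "threshold") < 1
  }, TRUE)
  expect_gt(mean(below), 0.5)
})
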