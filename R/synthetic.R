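#' Specify a synthetic case-table generator
#'
#' Describes case tables with the statistical structure the configurational
#' analysis assumes: a planted DNF ground truth over named crisp factors,
#' inert dichotomous and multivalue noise factors emulating the original
#' 11-factor roster (six dichotomous, five multivalue), optional independent
#' outcome flips with probability `outcome_flip_prob`, and optional emission
#' of pre/during rate pairs consistent with the outcome label so that
#' outcome derivation is exercised end to end.
#'
#' Noise enters through the outcome classification only — condition values
#' stay exact — matching the crisp-set setting where measurement error
#' manifests as a misclassified outcome.
#'
#' @param planted_model a [dnf_model()] (or list of conjunctions) over crisp
#'   factors; must be satisfiable and non-tautological on its factors.
#' @param n_cases number of cases (default 19).
#' @param n_noise_binary inert crisp factors; default tops the dichotomous
#'   factors (planted + noise) up to six.
#' @param n_noise_multivalue inert multivalue factors (default 5).
#' @param multivalue_levels level count per multivalue factor (default 3).
#' @param config_sampling `"uniform"` (iid uniform configurations),
#'   `"balanced"` (every planted-factor configuration observed at least once
#'   when `n_cases` allows, remainder uniform), or `"weighted"` (supply
#'   `config_weights` over the planted-factor configuration grid, in
#'   [expand.grid()] row order).
#' @param config_weights non-negative weights for `"weighted"` sampling.
#' @param outcome_flip_prob flip probability in `[0, 0.5)`.
#' @param outcome_name outcome column name (default `"improved"`).
#' @param rate_emission `NULL`, or a list with `threshold` (decline fraction
#'   the outcome encodes, default 0.10), `pre_meanlog`, `pre_sdlog`
#'   (lognormal baseline-rate parameters, defaulting to the 0.7-4.4 per
#'   1,000 resident-day spread of the fixture).
#' @param seed default RNG seed used by [generate_case_table()].
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(planted_model, n_cases = 19,
                           n_noise_binary = NULL, n_noise_multivalue = 5,
                           multivalue_levels = 3,
                           config_sampling = c("uniform", "balanced", "weighted"),
                           config_weights = NULL,
                           outcome_flip_prob = 0,
                           outcome_name = "improved",
                           rate_emission = NULL, seed = NULL) {
  if (!inherits(planted_model, "dnf_model")) {
    planted_model <- dnf_model(planted_model)
  }
  config_sampling <- match.arg(config_sampling)
  if (n_cases < 1) stop_spec("`n_cases` must be >= 1")
  if (outcome_flip_prob < 0 || outcome_flip_prob >= 0.5) {
    stop_spec("`outcome_flip_prob` must lie in [0, 0.5)")
  }
  pf <- model_factors(planted_model)
  grid <- expand.grid(rep(list(0:1), length(pf)), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- pf
  truth_vals <- eval_dnf_on_grid(planted_model, grid)
  if (!any(truth_vals)) stop_spec("planted model is unsatisfiable")
  if (all(truth_vals)) stop_spec("planted model is tautological on its factors")
  if (config_sampling == "weighted") {
    if (is.null(config_weights) || length(config_weights) != nrow(grid) ||
        any(config_weights < 0) || sum(config_weights) <= 0) {
      stop_spec("`config_weights` must be non-negative over the full configuration grid")
    }
  }
  if (is.null(n_noise_binary)) n_noise_binary <- max(0L, 6L - length(pf))
  if (!is.null(rate_emission)) {
    rate_emission <- utils::modifyList(
      list(threshold = 0.10, pre_meanlog = log(1.75), pre_sdlog = 0.45),
      rate_emission)
  }
  structure(list(planted_model = planted_model, planted_factors = pf,
                 n_cases = as.integer(n_cases),
                 n_noise_binary = as.integer(n_noise_binary),
                 n_noise_multivalue = as.integer(n_noise_multivalue),
                 multivalue_levels = as.integer(multivalue_levels),
                 config_sampling = config_sampling,
                 config_weights = config_weights,
                 outcome_flip_prob = outcome_flip_prob,
                 outcome_name = outcome_name,
                 rate_emission = rate_emission, seed = seed),
            class = "generator_spec")
}

#' Generate a synthetic case table with planted ground truth
#'
#' Samples factor configurations per the spec, evaluates the planted model
#' to obtain the true outcome, applies independent flips with probability
#' `outcome_flip_prob`, and either writes the (possibly flipped) outcome
#' column or, under rate emission, a pre/during rate pair whose relative
#' decline encodes it. Fully reproducible from the seed.
#'
#' @param spec a [generator_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return list with `table` (a [case_table()]) and `truth` (planted model,
#'   factors, true outcome vector, flip indicator).
#' @export
generate_case_table <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "generator_spec")) stop_spec("`spec` must be a generator_spec")
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_cases
  pf <- spec$planted_factors
  grid <- expand.grid(rep(list(0:1), length(pf)), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- pf

  rows <- switch(spec$config_sampling,
    uniform = sample.int(nrow(grid), n, replace = TRUE),
    balanced = {
      base <- if (n >= nrow(grid)) seq_len(nrow(grid)) else integer()
      extra <- sample.int(nrow(grid), n - length(base), replace = TRUE)
      sample(c(base, extra))
    },
    weighted = sample.int(nrow(grid), n, replace = TRUE,
                          prob = spec$config_weights))
  conf <- grid[rows, , drop = FALSE]
  rownames(conf) <- NULL

  y_true <- as.integer(eval_dnf_on_grid(spec$planted_model, conf))
  flip <- if (spec$outcome_flip_prob > 0) {
    stats::rbinom(n, 1L, spec$outcome_flip_prob)
  } else {
    rep(0L, n)
  }
  y <- as.integer(xor(y_true, flip))

  df <- data.frame(case_id = sprintf("case_%02d", seq_len(n)), conf,
                   check.names = FALSE)
  decls <- lapply(pf, factor_decl)
  if (spec$n_noise_binary > 0) {
    for (i in seq_len(spec$n_noise_binary)) {
      nm <- sprintf("noise_bin_%d", i)
      df[[nm]] <- stats::rbinom(n, 1L, 0.5)
      decls[[length(decls) + 1L]] <- factor_decl(nm)
    }
  }
  if (spec$n_noise_multivalue > 0) {
    lv <- letters[seq_len(spec$multivalue_levels)]
    for (i in seq_len(spec$n_noise_multivalue)) {
      nm <- sprintf("noise_mv_%d", i)
      df[[nm]] <- sample(lv, n, replace = TRUE)
      decls[[length(decls) + 1L]] <- factor_decl(nm, "multivalue", levels = lv)
    }
  }

  outcomes <- character()
  if (is.null(spec$rate_emission)) {
    df[[spec$outcome_name]] <- y
    outcomes <- spec$outcome_name
  } else {
    re <- spec$rate_emission
    pre <- stats::rlnorm(n, re$pre_meanlog, re$pre_sdlog)
    decline <- ifelse(y == 1L,
                      stats::runif(n, re$threshold, 0.6),
                      stats::runif(n, -0.3, re$threshold - 1e-6))
    df$pre_rate <- pre
    df$during_rate <- pre * (1 - decline)
    decls[[length(decls) + 1L]] <- factor_decl("pre_rate", "numeric")
    decls[[length(decls) + 1L]] <- factor_decl("during_rate", "numeric")
  }

  table <- case_table(df, decls, outcomes = outcomes, id_col = "case_id")
  list(table = table,
       truth = list(model = spec$planted_model, factors = pf,
                    outcome_name = spec$outcome_name,
                    y_true = y_true, flipped = flip,
                    n_flipped = sum(flip)))
}

#' Recover the planted model from synthetic replicates
#'
#' Per replicate: generates a table, (if rates were emitted) derives the
#' outcome, then walks the consistency-threshold schedule over the planted
#' factors — truth table, minimization, and a logical-equivalence check of
#' every returned minimal solution against the planted model on the full
#' configuration space of the planted factors. Aggregates the exact-recovery
#' rate with its binomial standard error plus per-replicate term precision
#' and recall.
#'
#' @param spec a [generator_spec()].
#' @param n_reps number of replicates.
#' @param seeds per-replicate seeds (default `base_seed + 1:n_reps`).
#' @param base_seed offset used when `seeds` is `NULL` (default
#'   `spec$seed %||% 0`).
#' @param strategy minimization strategy.
#' @param start,step,floor threshold schedule.
#' @return a `recovery_result`: `replicates` data.frame (`seed`,
#'   `recovered`, `ambiguous`, `threshold`, `term_precision`,
#'   `term_recall`), `recovery_rate`, `se` (binomial), `n_reps`.
#' @export
recovery_experiment <- function(spec, n_reps, seeds = NULL,
                                base_seed = spec$seed %||% 0,
                                strategy = "parsimonious",
                                start = 1, step = 0.05, floor = 0.5) {
  if (n_reps < 1) stop_usage("`n_reps` must be >= 1")
  if (is.null(seeds)) seeds <- base_seed + seq_len(n_reps)
  if (length(seeds) != n_reps) stop_usage("`seeds` must have length `n_reps`")
  schedule <- threshold_schedule(start, step, floor)
  planted_sigs <- vapply(spec$planted_model$terms, conj_signature, "")

  reps <- lapply(seeds, function(sd) {
    gen <- generate_case_table(spec, seed = sd)
    ct <- gen$table
    if (!is.null(spec$rate_emission)) {
      oc <- derive_decline_outcomes(ct$data$pre_rate, ct$data$during_rate,
                                    spec$rate_emission$threshold,
                                    names = spec$outcome_name)
      ct$data[[spec$outcome_name]] <- oc[[1]]
      ct$outcomes <- spec$outcome_name
    }
    rec <- FALSE; amb <- FALSE; thr <- NA_real_
    prec <- NA_real_; recall <- NA_real_
    for (t in schedule) {
      tt <- build_truth_table(ct, spec$planted_factors, spec$outcome_name, t)
      models <- tryCatch(minimize(tt, strategy),
                         csqca_no_model_error = function(e) NULL,
                         csqca_degenerate_error = function(e) NULL)
      if (is.null(models)) next
      thr <- t
      amb <- isTRUE(attr(models, "ambiguous"))
      rec <- all(vapply(models, dnf_equivalent, TRUE, b = spec$planted_model,
                        factors = spec$planted_factors))
      got <- vapply(models[[1]]$terms, conj_signature, "")
      prec <- mean(got %in% planted_sigs)
      recall <- mean(planted_sigs %in% got)
      break
    }
    data.frame(seed = sd, recovered = rec, ambiguous = amb, threshold = thr,
               term_precision = prec, term_recall = recall)
  })
  replicates <- do.call(rbind, reps)
  rate <- mean(replicates$recovered)
  structure(list(replicates = replicates,
                 recovery_rate = rate,
                 se = sqrt(rate * (1 - rate) / n_reps),
                 n_reps = n_reps),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery_result> %d replicates: exact-recovery rate %.2f (SE %.3f)\n",
              x$n_reps, x$recovery_rate, x$se))
  invisible(x)
}
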