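#' Model-selection criteria for the dual-outcome evaluation
#'
#' Defaults encode the study's evaluation rule: a model qualifies when it
#' reaches at least 80% solution consistency and 80% solution coverage,
#' every term keeps at least 15% unique coverage, exactly one minimal
#' solution exists (no model ambiguity), and the two target outcomes are
#' explained over the same factor set (`same_factors = "nested"` accepts a
#' nested superset — the stricter outcome may need one extra condition;
#' `"exact"` requires identical sets).
#'
#' @param min_consistency,min_coverage,min_unique_coverage fractions in
#'   (0, 1].
#' @param require_no_ambiguity reject truth tables with several equally
#'   minimal solutions (after unique-coverage pruning).
#' @param same_factors `"nested"`, `"exact"` or `"off"`.
#' @return a `selection_criteria` list.
#' @export
selection_criteria <- function(min_consistency = 0.80, min_coverage = 0.80,
                               min_unique_coverage = 0.15,
                               require_no_ambiguity = TRUE,
                               same_factors = c("nested", "exact", "off")) {
  same_factors <- match.arg(same_factors)
  for (v in c(min_consistency, min_coverage)) {
    if (v <= 0 || v > 1) stop_usage("criteria fractions must lie in (0, 1]")
  }
  if (min_unique_coverage < 0 || min_unique_coverage > 1) {
    stop_usage("`min_unique_coverage` must lie in [0, 1]")
  }
  structure(list(min_consistency = min_consistency,
                 min_coverage = min_coverage,
                 min_unique_coverage = min_unique_coverage,
                 require_no_ambiguity = isTRUE(require_no_ambiguity),
                 same_factors = same_factors),
            class = "selection_criteria")
}

#' Data reduction: msc enumeration and candidate factor subsets
#'
#' Runs [enumerate_msc()] for each outcome and collects the factors
#' appearing among the top-ranked configurations as modelling candidates.
#' Substantive judgement about which candidates to carry forward ("logic,
#' theory, and prior knowledge") is not automated: pass `allow_list` to fix
#' the candidate subset(s) explicitly.
#'
#' @param ct a [case_table()].
#' @param outcomes outcome names (one or more).
#' @param max_order,start,step,floor forwarded to [enumerate_msc()].
#' @param top_n how many top-ranked configurations feed the candidate set.
#' @param allow_list optional character vector (or list of vectors) of
#'   factor names overriding the derived candidates.
#' @return a `reduction_report` list: per outcome the `msc_result`, plus
#'   `candidates` (list of factor subsets).
#' @export
reduce_factors <- function(ct, outcomes, max_order = 4, start = 1,
                           step = 0.05, floor = 0.5, top_n = 10,
                           allow_list = NULL) {
  msc <- lapply(outcomes, function(oc) {
    enumerate_msc(ct, oc, max_order = max_order, start = start,
                  step = step, floor = floor)
  })
  names(msc) <- outcomes
  if (!is.null(allow_list)) {
    candidates <- if (is.list(allow_list)) allow_list else list(allow_list)
  } else {
    candidates <- lapply(msc, function(m) {
      if (!nrow(m)) return(character())
      top <- utils::head(m, top_n)
      sort(unique(unlist(lapply(top$formula, formula_factors))))
    })
    candidates <- unique(unname(candidates))
    candidates <- candidates[lengths(candidates) > 0]
  }
  structure(list(msc = msc, candidates = candidates,
                 overridden = !is.null(allow_list)),
            class = "reduction_report")
}

formula_factors <- function(formula) {
  lits <- strsplit(formula, "*", fixed = TRUE)[[1]]
  vapply(lits, function(l) sub("^~", "", sub("=.*$", "", l)), "",
         USE.NAMES = FALSE)
}

#' Prune model terms below a unique-coverage floor
#'
#' Removes, from each model, terms whose unique coverage falls below
#' `min_unique`; models whose term sets coincide after pruning are merged
#' and models losing all terms are dropped. Pruning can only shrink the set
#' of covered cases, so it never lowers solution consistency; the pruned
#' coverage is recomputed.
#'
#' @param models list of [dnf_model()]s (as returned by [minimize()]).
#' @param ct a [case_table()].
#' @param outcome a declared binary outcome.
#' @param min_unique unique-coverage floor in `[0, 1]` (default 0.15).
#' @return list with `models` (pruned, deduplicated) and `pruned` (a
#'   data.frame of removed terms with their unique coverage).
#' @export
prune_terms_by_unique_coverage <- function(models, ct, outcome,
                                           min_unique = 0.15) {
  if (!length(models)) stop_usage("`models` must be non-empty")
  if (inherits(models, "dnf_model")) models <- list(models)
  dropped <- list()
  kept <- list()
  for (mod in models) {
    met <- model_metrics(mod, ct, outcome)
    low <- met$terms$unique_coverage < min_unique - EPS
    if (any(low)) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        model = format(mod),
        term = met$terms$formula[low],
        unique_coverage = met$terms$unique_coverage[low],
        stringsAsFactors = FALSE)
    }
    if (all(low)) next
    kept[[length(kept) + 1L]] <- dnf_model(met$model$terms[!low],
                                           strategy = mod$strategy,
                                           outcome = mod$outcome)
  }
  if (length(kept)) {
    kept <- kept[!duplicated(vapply(kept, model_signature, ""))]
    kept <- kept[order(vapply(kept, model_signature, ""))]
  }
  list(models = kept,
       pruned = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(model = character(), term = character(),
                    unique_coverage = numeric(), stringsAsFactors = FALSE))
}

#' Model development for one or two target outcomes
#'
#' For each outcome, walks the consistency-threshold schedule from `start`
#' downwards: builds the truth table over the outcome's factor subset,
#' minimizes it, prunes low-yield terms, and evaluates the selection
#' criteria. The first threshold producing a qualifying model wins; every
#' tried threshold and its rejection reason is recorded. With two outcomes
#' the dual-outcome constraint of the criteria is then checked across the
#' selected models' factor subsets.
#'
#' @param ct a [case_table()].
#' @param outcomes one or two declared outcome names.
#' @param factor_subsets a character vector (used for every outcome) or a
#'   named list of per-outcome crisp factor subsets.
#' @param criteria a [selection_criteria()].
#' @param start,step,floor the threshold schedule.
#' @param strategy minimization strategy, default `"parsimonious"`.
#' @return an `analysis_report` (see [render_report()]).
#' @examples
#' ct <- optimistic_facilities()
#' rep <- develop_models(ct, c("decline10", "decline20"),
#'   list(decline10 = c("don_turnover", "support", "low_baseline"),
#'        decline20 = c("don_turnover", "support", "low_baseline", "chess")))
#' @export
develop_models <- function(ct, outcomes, factor_subsets,
                           criteria = selection_criteria(),
                           start = 1, step = 0.05, floor = 0.5,
                           strategy = "parsimonious") {
  if (!is.list(factor_subsets)) {
    factor_subsets <- stats::setNames(
      rep(list(factor_subsets), length(outcomes)), outcomes)
  }
  missing_sub <- setdiff(outcomes, names(factor_subsets))
  if (length(missing_sub)) {
    stop_usage(sprintf("no factor subset for outcome(s): %s",
                       paste(missing_sub, collapse = ", ")))
  }
  schedule <- threshold_schedule(start, step, floor)
  per_outcome <- lapply(outcomes, function(oc) {
    develop_one(ct, oc, factor_subsets[[oc]], criteria, schedule, strategy)
  })
  names(per_outcome) <- outcomes

  dual_ok <- TRUE
  dual_reason <- NULL
  if (length(outcomes) == 2 && criteria$same_factors != "off") {
    a <- per_outcome[[1]]; b <- per_outcome[[2]]
    if (!a$qualifies || !b$qualifies) {
      dual_ok <- FALSE
      dual_reason <- "at least one outcome has no qualifying model"
    } else {
      fa <- sort(a$factor_subset); fb <- sort(b$factor_subset)
      dual_ok <- if (criteria$same_factors == "exact") {
        identical(fa, fb)
      } else {
        all(fa %in% fb) || all(fb %in% fa)
      }
      if (!dual_ok) dual_reason <- "selected models use non-nested factor sets"
    }
  }
  thr <- vapply(per_outcome, function(x) x$threshold %||% NA_real_, 0)
  structure(list(
    outcomes = per_outcome,
    criteria = criteria,
    strategy = strategy,
    schedule = schedule,
    dual_outcome_ok = dual_ok,
    dual_outcome_reason = dual_reason,
    thresholds_differ = length(unique(thr[!is.na(thr)])) > 1,
    qualifies = dual_ok && all(vapply(per_outcome, `[[`, TRUE, "qualifies"))
  ), class = "analysis_report")
}

develop_one <- function(ct, outcome, subset, criteria, schedule, strategy) {
  attempts <- list()
  for (thr in schedule) {
    tt <- build_truth_table(ct, subset, outcome, thr)
    step_result <- tryCatch({
      models <- minimize(tt, strategy)
      pruned <- prune_terms_by_unique_coverage(
        models, ct, outcome, criteria$min_unique_coverage)
      if (!length(pruned$models)) {
        list(reason = "all terms pruned below unique-coverage floor")
      } else if (criteria$require_no_ambiguity && length(pruned$models) > 1) {
        list(reason = sprintf("model ambiguity (%d equally minimal solutions)",
                              length(pruned$models)))
      } else {
        model <- pruned$models[[1]]
        met <- model_metrics(model, ct, outcome)
        if (met$consistency < criteria$min_consistency - EPS) {
          list(reason = sprintf("solution consistency %.2f below %.2f",
                                met$consistency, criteria$min_consistency))
        } else if (met$coverage < criteria$min_coverage - EPS) {
          list(reason = sprintf("solution coverage %.2f below %.2f",
                                met$coverage, criteria$min_coverage))
        } else {
          list(model = met$model, metrics = met, pruned = pruned$pruned,
               n_solutions_raw = length(models))
        }
      }
    },
    csqca_no_model_error = function(e) list(reason = "no output-1 truth-table row"),
    csqca_degenerate_error = function(e) list(reason = "degenerate (tautological) solution"),
    csqca_undefined_metric_error = function(e) list(reason = conditionMessage(e)))
    attempts[[length(attempts) + 1L]] <- data.frame(
      threshold = thr,
      accepted = is.null(step_result$reason),
      reason = step_result$reason %||% "accepted",
      stringsAsFactors = FALSE)
    if (is.null(step_result$reason)) {
      return(list(outcome = outcome, factor_subset = subset, qualifies = TRUE,
                  threshold = thr, model = step_result$model,
                  metrics = step_result$metrics,
                  partition = partition_summary(step_result$model, ct, outcome),
                  pruned_terms = step_result$pruned,
                  n_solutions_raw = step_result$n_solutions_raw,
                  attempts = do.call(rbind, attempts)))
    }
    # the schedule is lowered only while the truth table is unworkable
    # (no minimizable output-1 structure); a model that exists but fails
    # the criteria is a rejection, not a reason to relax consistency
    if (!step_result$reason %in%
          c("no output-1 truth-table row",
            "degenerate (tautological) solution")) {
      break
    }
  }
  list(outcome = outcome, factor_subset = subset, qualifies = FALSE,
       threshold = NULL, model = NULL, metrics = NULL, partition = NULL,
       pruned_terms = NULL, n_solutions_raw = 0L,
       attempts = do.call(rbind, attempts))
}

#' Run the full configurational analysis from a single config
#'
#' End-to-end composition: load (or accept) a case table, optionally derive
#' decline outcomes from pre/during rate columns, run data reduction (msc),
#' then model development against the selection criteria, and assess the
#' necessity/sufficiency of every single condition. Deterministic given the
#' config: two runs produce byte-identical JSON reports.
#'
#' @param config a list, or path to a YAML/JSON config file, with elements:
#'   * `table`: `"optimistic"` for the packaged fixture, a `case_table`, or
#'     a CSV path (then `schema` is required);
#'   * `outcomes`: outcome names (default: all declared);
#'   * `derive_outcomes`: optional list `(pre, during, thresholds)` naming
#'     rate columns from which to derive the outcome columns;
#'   * `factor_subsets`: per-outcome factor subsets (allow-list); when
#'     absent the msc-derived candidates are used;
#'   * `criteria`: arguments to [selection_criteria()];
#'   * `schedule`: list `(start, step, floor)`;
#'   * `max_order`: msc order cap (default 4);
#'   * `strategy`: minimization strategy.
#' @return an `analysis_report` with the reduction report attached.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config, simplifyVector = TRUE,
                         simplifyDataFrame = FALSE)
    }
  }
  ct <- pipeline_table(config)
  if (!is.null(config$derive_outcomes)) {
    d <- config$derive_outcomes
    oc <- derive_decline_outcomes(ct$data[[d$pre]], ct$data[[d$during]],
                                  as.numeric(d$thresholds))
    for (nm in names(oc)) ct$data[[nm]] <- oc[[nm]]
    ct$outcomes <- unique(c(ct$outcomes, names(oc)))
  }
  outcomes <- config$outcomes %||% ct$outcomes
  if (!length(outcomes)) stop_usage("config names no outcomes")
  sched <- config$schedule %||% list()
  start <- sched$start %||% 1
  step <- sched$step %||% 0.05
  floor <- sched$floor %||% 0.5
  criteria <- do.call(selection_criteria, config$criteria %||% list())
  strategy <- config$strategy %||% "parsimonious"

  reduction <- reduce_factors(
    ct, outcomes, max_order = config$max_order %||% 4,
    start = start, step = step, floor = floor,
    allow_list = NULL)

  subsets <- config$factor_subsets
  if (is.null(subsets)) {
    if (!length(reduction$candidates)) {
      stop_no_model("data reduction produced no candidate factors and no allow-list was given")
    }
    subsets <- stats::setNames(
      rep(list(sort(unique(unlist(reduction$candidates)))), length(outcomes)),
      outcomes)
  }
  report <- develop_models(ct, outcomes, subsets, criteria = criteria,
                           start = start, step = step, floor = floor,
                           strategy = strategy)
  report$reduction <- reduction
  report$necessity <- necessity_table(ct, outcomes, subsets)
  report$table_summary <- list(n_cases = n_cases(ct),
                               factors = condition_factor_names(ct),
                               outcomes = outcomes)
  report
}

pipeline_table <- function(config) {
  tab <- config$table
  if (inherits(tab, "case_table")) return(tab)
  if (is.character(tab) && identical(tab, "optimistic")) {
    return(optimistic_facilities())
  }
  if (is.character(tab)) {
    if (is.null(config$schema)) stop_usage("a CSV table needs a `schema`")
    return(load_case_table(tab, config$schema))
  }
  stop_usage("config `table` must be a case_table, 'optimistic', or a CSV path")
}

# necessity/sufficiency of every single condition (both polarities for
# crisp factors) over the union of the modelled factor subsets
necessity_table <- function(ct, outcomes, subsets) {
  fac <- sort(unique(unlist(subsets)))
  rows <- list()
  for (oc in outcomes) {
    for (f in fac) {
      for (v in ct$factors[[f]]$levels) {
        conj <- conjunction(.lits = stats::setNames(v, f))
        res <- tryCatch(assess_necessity_sufficiency(conj, ct, oc),
                        csqca_undefined_metric_error = function(e) NULL)
        if (is.null(res)) next
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = oc, condition = res$condition,
          sufficient = res$sufficient, necessary = res$necessary,
          consistency = res$consistency, coverage = res$coverage,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
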