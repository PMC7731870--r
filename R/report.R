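#' Render an analysis report as text or JSON
#'
#' Text output gives plain-language solution sentences, the metric table
#' and the path-partition summary per outcome; when no model qualifies it
#' states the lowest threshold tried and every rejection reason. JSON output
#' is schema-stable (models as lists of `{factor, value}` literals, metric
#' and partition blocks) and round-trips: parsing it back reproduces every
#' count and term exactly. Rendering is deterministic — identical reports
#' yield byte-identical documents.
#'
#' @param report an `analysis_report` from [develop_models()] or
#'   [run_pipeline()].
#' @param format `"text"` or `"json"`.
#' @return a character scalar (the document).
#' @examples
#' ct <- optimistic_facilities()
#' rep <- develop_models(ct, "decline10",
#'                       c("don_turnover", "support", "low_baseline"))
#' cat(render_report(rep, "text"))
#' @export
render_report <- function(report, format = c("text", "json")) {
  if (!inherits(report, "analysis_report")) {
    stop_usage("`report` must be an analysis_report")
  }
  if (!is.character(format) || !all(format %in% c("text", "json"))) {
    stop_usage(sprintf("unknown report format '%s'", format[1]))
  }
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(
      report_to_list(report), auto_unbox = TRUE, pretty = TRUE,
      digits = NA, null = "null")))
  }
  paste0(paste(report_text_lines(report), collapse = "\n"), "\n")
}

serialize_model <- function(model) {
  list(
    formula = format(model),
    strategy = model$strategy,
    terms = lapply(model$terms, function(tm) {
      lapply(names(tm), function(f) list(factor = f, value = unname(tm[[f]])))
    }))
}

serialize_metrics <- function(met) {
  list(
    consistency = met$consistency,
    coverage = met$coverage,
    n_covered = met$n_covered,
    n_covered_positive = met$n_covered_positive,
    n_outcome = met$n_outcome,
    consistency_display = sprintf("%d/%d = %.2f", met$n_covered_positive,
                                  met$n_covered, round(met$consistency, 2)),
    coverage_display = sprintf("%d/%d = %.2f", met$n_covered_positive,
                               met$n_outcome, round(met$coverage, 2)),
    terms = lapply(seq_len(nrow(met$terms)), function(i) {
      as.list(met$terms[i, c("formula", "raw_coverage", "unique_coverage",
                             "n_raw", "n_only")])
    }))
}

serialize_partition <- function(part) {
  list(
    n_outcome = part$n_outcome,
    paths = lapply(seq_len(nrow(part$terms)), function(i) {
      list(formula = part$terms$formula[i],
           n_exclusive = part$terms$n_exclusive[i],
           cases = strsplit(part$terms$cases[i], ",", fixed = TRUE)[[1]])
    }),
    overlaps = lapply(seq_along(part$overlaps), function(i) {
      list(paths = names(part$overlaps)[i],
           n = unname(part$overlaps[[i]]))
    }),
    uncovered = part$uncovered,
    uncovered_cases = as.list(part$uncovered_cases))
}

report_to_list <- function(report) {
  out <- list(
    qualifies = report$qualifies,
    strategy = report$strategy,
    schedule = as.list(report$schedule),
    criteria = unclass(report$criteria),
    dual_outcome_ok = report$dual_outcome_ok,
    dual_outcome_reason = report$dual_outcome_reason,
    thresholds_differ = report$thresholds_differ,
    outcomes = lapply(report$outcomes, function(oc) {
      base <- list(
        outcome = oc$outcome,
        factor_subset = as.list(oc$factor_subset),
        qualifies = oc$qualifies,
        threshold = oc$threshold,
        attempts = lapply(seq_len(nrow(oc$attempts)), function(i) {
          as.list(oc$attempts[i, ])
        }))
      if (oc$qualifies) {
        base$model <- serialize_model(oc$model)
        base$metrics <- serialize_metrics(oc$metrics)
        base$partition <- serialize_partition(oc$partition)
        base$pruned_terms <- lapply(seq_len(nrow(oc$pruned_terms)),
                                    function(i) as.list(oc$pruned_terms[i, ]))
      }
      base
    }))
  if (!is.null(report$reduction)) {
    out$reduction <- list(
      overridden = report$reduction$overridden,
      candidates = lapply(report$reduction$candidates, as.list),
      msc = lapply(report$reduction$msc, function(m) {
        list(threshold = attr(m, "threshold"),
             outcome = attr(m, "outcome"),
             configurations = lapply(seq_len(nrow(m)), function(i) {
               as.list(as.data.frame(m)[i, ])
             }))
      }))
  }
  if (!is.null(report$necessity)) {
    out$necessity <- lapply(seq_len(nrow(report$necessity)),
                            function(i) as.list(report$necessity[i, ]))
  }
  if (!is.null(report$table_summary)) out$table_summary <- report$table_summary
  out
}

plain_language <- function(model) {
  phrases <- vapply(model$terms, function(tm) {
    lit <- ifelse(unname(tm) == "1", toupper(names(tm)),
                  ifelse(unname(tm) == "0", paste0("not ", toupper(names(tm))),
                         paste0(toupper(names(tm)), " = ", unname(tm))))
    paste(lit, collapse = " AND ")
  }, "")
  paste(phrases, collapse = "; OR ")
}

report_text_lines <- function(report) {
  lines <- c("Configurational analysis report",
             "===============================",
             sprintf("strategy: %s; schedule: %s", report$strategy,
                     paste(sprintf("%.2f", report$schedule), collapse = " ")),
             sprintf("overall qualifying: %s", report$qualifies))
  if (!report$dual_outcome_ok && !is.null(report$dual_outcome_reason)) {
    lines <- c(lines, sprintf("dual-outcome check failed: %s",
                              report$dual_outcome_reason))
  }
  for (oc in report$outcomes) {
    lines <- c(lines, "",
               sprintf("Outcome '%s' over factors {%s}", oc$outcome,
                       paste(oc$factor_subset, collapse = ", ")))
    if (!oc$qualifies) {
      lines <- c(lines,
                 sprintf("  no qualifying model down to threshold %.2f",
                         min(oc$attempts$threshold)),
                 sprintf("  threshold %.2f: %s", oc$attempts$threshold,
                         oc$attempts$reason))
      next
    }
    met <- oc$metrics
    lines <- c(lines,
               sprintf("  consistency threshold used: %.2f", oc$threshold),
               sprintf("  solution: %s", format(oc$model)),
               sprintf("  in plain language: %s", plain_language(oc$model)),
               sprintf("  consistency %d/%d = %.0f%%; coverage %d/%d = %.0f%%",
                       met$n_covered_positive, met$n_covered,
                       round(100 * met$consistency),
                       met$n_covered_positive, met$n_outcome,
                       round(100 * met$coverage)))
    for (i in seq_len(nrow(met$terms))) {
      lines <- c(lines, sprintf(
        "    path [%s]: raw coverage %d/%d, unique coverage %d/%d",
        met$terms$formula[i], met$terms$n_raw[i], met$n_outcome,
        met$terms$n_only[i], met$n_outcome))
    }
    p <- oc$partition
    part_counts <- c(p$terms$n_exclusive, unname(unlist(p$overlaps)))
    lines <- c(lines, sprintf(
      "  partition of the %d outcome cases: %s with %d uncovered (%s)",
      p$n_outcome, paste(part_counts, collapse = " / "), p$uncovered,
      paste(p$uncovered_cases, collapse = ", ")))
    if (!is.null(oc$pruned_terms) && nrow(oc$pruned_terms)) {
      lines <- c(lines, sprintf(
        "  pruned term [%s] (unique coverage %.2f below floor)",
        oc$pruned_terms$term, oc$pruned_terms$unique_coverage))
    }
  }
  if (!is.null(report$necessity)) {
    nec <- report$necessity
    lines <- c(lines, "", "Necessity / sufficiency of single conditions:")
    suff <- nec[nec$sufficient, , drop = FALSE]
    necs <- nec[nec$necessary, , drop = FALSE]
    lines <- c(lines,
               if (nrow(suff)) sprintf("  sufficient for %s: %s", suff$outcome,
                                       suff$condition)
               else "  no single condition is sufficient for any outcome",
               if (nrow(necs)) sprintf("  necessary for %s: %s", necs$outcome,
                                       necs$condition)
               else "  no single condition is necessary for any outcome")
  }
  lines
}
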