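#' Solution consistency, coverage and path partition of a model
#'
#' Evaluates a DNF model against the cases: solution consistency is the
#' fraction of covered cases that exhibit the outcome; solution coverage the
#' fraction of outcome cases that are covered. Per path (term) the raw
#' coverage (outcome cases satisfying the path) and unique coverage (outcome
#' cases satisfying that path and no other) are reported, together with the
#' partition of the outcome cases into path-exclusive groups, overlaps and
#' the uncovered remainder — the counts behind a solution Venn diagram.
#'
#' Paths are reordered for presentation: more literals first, then higher
#' raw coverage, then alphabetically.
#'
#' @param model a [dnf_model()].
#' @param ct a [case_table()].
#' @param outcome a declared binary outcome.
#' @return a `model_metrics` list: `consistency`, `coverage` (fractions),
#'   `n_covered`, `n_covered_positive`, `n_outcome`, a `terms` data.frame
#'   (`formula`, `raw_coverage`, `unique_coverage`, `n_raw`, `n_only`), and
#'   `partition` (`one_path`, `multi_path`, `uncovered`, `uncovered_cases`,
#'   `overlap_counts`).
#' @examples
#' ct <- optimistic_facilities()
#' m <- dnf_model(list(conjunction(don_turnover = 1),
#'                     conjunction(support = 1, low_baseline = 0)))
#' model_metrics(m, ct, "decline10")
#' @export
model_metrics <- function(model, ct, outcome) {
  y <- check_outcome(ct, outcome)
  n_out <- sum(y == 1L)
  if (!n_out) stop_undefined("no outcome-positive case")
  sat <- vapply(model$terms, function(tm) satisfies(ct, tm),
                logical(n_cases(ct)))
  sat <- matrix(sat, nrow = n_cases(ct))
  if (!any(sat)) stop_undefined("model satisfied by no case")

  # presentation order: specific paths first, then by raw coverage
  raw_n <- colSums(sat & y == 1L)
  ord <- order(-lengths(model$terms), -raw_n,
               vapply(model$terms, format, ""))
  model$terms <- model$terms[ord]
  sat <- sat[, ord, drop = FALSE]
  raw_n <- raw_n[ord]

  covered <- rowSums(sat) > 0
  n_cov <- sum(covered)
  n_cov_pos <- sum(covered & y == 1L)
  hits_per_pos <- rowSums(sat)[y == 1L]
  only_n <- colSums(sat & y == 1L & rowSums(sat) == 1)

  pos_pattern <- apply(sat[y == 1L, , drop = FALSE], 1, function(r) {
    paste(which(r), collapse = "&")
  })
  pos_pattern <- pos_pattern[nzchar(pos_pattern)]
  overlap <- table(pos_pattern)
  overlap <- stats::setNames(as.integer(overlap), vapply(
    names(overlap), function(p) {
      idx <- as.integer(strsplit(p, "&", fixed = TRUE)[[1]])
      paste(vapply(model$terms[idx], format, ""), collapse = " & ")
    }, ""))

  structure(list(
    model = model,
    outcome = outcome,
    consistency = n_cov_pos / n_cov,
    coverage = n_cov_pos / n_out,
    n_covered = n_cov,
    n_covered_positive = n_cov_pos,
    n_outcome = n_out,
    terms = data.frame(
      formula = vapply(model$terms, format, ""),
      raw_coverage = raw_n / n_out,
      unique_coverage = only_n / n_out,
      n_raw = as.integer(raw_n),
      n_only = as.integer(only_n),
      stringsAsFactors = FALSE),
    partition = list(
      one_path = sum(hits_per_pos == 1),
      multi_path = sum(hits_per_pos > 1),
      uncovered = sum(hits_per_pos == 0),
      uncovered_cases = ct$case_ids[y == 1L & !covered],
      overlap_counts = overlap)
  ), class = "model_metrics")
}

#' @export
print.model_metrics <- function(x, ...) {
  cat(sprintf("<model_metrics> %s\n", format(x$model)))
  cat(sprintf("  consistency %d/%d = %.2f; coverage %d/%d = %.2f\n",
              x$n_covered_positive, x$n_covered, x$consistency,
              x$n_covered_positive, x$n_outcome, x$coverage))
  print(x$terms, row.names = FALSE, digits = 3)
  p <- x$partition
  cat(sprintf("  partition: %d one-path, %d multi-path, %d uncovered (%s)\n",
              p$one_path, p$multi_path, p$uncovered,
              paste(p$uncovered_cases, collapse = ", ")))
  invisible(x)
}

#' Path-partition summary of a solution model
#'
#' The counts that a solution Venn diagram would display: for each path the
#' outcome cases covered by that path only, each overlap of paths, and the
#' uncovered outcome cases with their ids.
#'
#' @inheritParams model_metrics
#' @return a `partition_summary` list with `terms` (formula, exclusive count
#'   and ids), `overlaps`, `uncovered` and `n_outcome`.
#' @export
partition_summary <- function(model, ct, outcome) {
  met <- model_metrics(model, ct, outcome)
  model <- met$model
  y <- check_outcome(ct, outcome)
  sat <- vapply(model$terms, function(tm) satisfies(ct, tm),
                logical(n_cases(ct)))
  sat <- matrix(sat, nrow = n_cases(ct))
  pos <- y == 1L
  excl <- lapply(seq_along(model$terms), function(i) {
    ct$case_ids[pos & sat[, i] & rowSums(sat) == 1]
  })
  structure(list(
    outcome = outcome,
    n_outcome = met$n_outcome,
    terms = data.frame(
      formula = met$terms$formula,
      n_exclusive = lengths(excl),
      cases = vapply(excl, paste, "", collapse = ","),
      stringsAsFactors = FALSE),
    overlaps = met$partition$overlap_counts[
      grepl(" & ", names(met$partition$overlap_counts), fixed = TRUE)],
    uncovered = met$partition$uncovered,
    uncovered_cases = met$partition$uncovered_cases
  ), class = "partition_summary")
}

#' @export
print.partition_summary <- function(x, ...) {
  cat(sprintf("<partition_summary> outcome '%s' (%d outcome cases)\n",
              x$outcome, x$n_outcome))
  for (i in seq_len(nrow(x$terms))) {
    cat(sprintf("  only [%s]: %d (%s)\n", x$terms$formula[i],
                x$terms$n_exclusive[i], x$terms$cases[i]))
  }
  for (nm in names(x$overlaps)) {
    cat(sprintf("  overlap [%s]: %d\n", nm, x$overlaps[[nm]]))
  }
  cat(sprintf("  uncovered: %d (%s)\n", x$uncovered,
              paste(x$uncovered_cases, collapse = ", ")))
  invisible(x)
}
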