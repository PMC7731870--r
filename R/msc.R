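#' Enumerate minimally sufficient conditions under a threshold schedule
#'
#' Considers every conjunction of 1..`max_order` literals over the table's
#' condition factors (crisp factors contribute presence and negation
#' literals, multivalue factors one literal per declared level) that is
#' instantiated by at least one case. Starting from `start` the consistency
#' cutoff is lowered by `step` decrements until at least one conjunction
#' qualifies (or `floor` is passed). A qualifying conjunction is *minimally*
#' sufficient: no proper sub-conjunction also meets the cutoff. Results are
#' ranked by coverage (descending), then fewer literals, then alphabetically
#' by formula.
#'
#' @param ct a [case_table()].
#' @param outcome a declared binary outcome name.
#' @param max_order maximum number of literals per conjunction (default 4).
#' @param start starting consistency cutoff in (0, 1] (default 1).
#' @param step decrement between successive cutoffs (default 0.05).
#' @param floor lowest cutoff tried (default 0.5).
#' @param factors optional subset of condition factors to enumerate over;
#'   default all crisp and multivalue factors.
#' @return an `msc_result`: data.frame with columns `formula`, `order`,
#'   `consistency`, `coverage`, `n_satisfying`, `n_positive` and attributes
#'   `threshold` (the cutoff actually used, or the floor when empty),
#'   `schedule`, `outcome`. Zero rows when nothing qualifies at the floor.
#' @examples
#' ct <- optimistic_facilities()
#' head(enumerate_msc(ct, "decline10"))
#' @export
enumerate_msc <- function(ct, outcome, max_order = 4, start = 1,
                          step = 0.05, floor = 0.5, factors = NULL) {
  y <- check_outcome(ct, outcome)
  if (max_order < 1) stop_usage("`max_order` must be >= 1")
  if (start <= 0 || start > 1) stop_usage("`start` must lie in (0, 1]")
  if (step <= 0) stop_usage("`step` must be > 0")
  if (floor <= 0 || floor > start) stop_usage("`floor` must lie in (0, start]")
  fnames <- factors %||% condition_factor_names(ct)
  if (!length(fnames)) stop_schema("no condition factors to enumerate over")
  if (!all(fnames %in% condition_factor_names(ct))) {
    stop_schema("`factors` contains an undeclared or numeric factor")
  }

  cand <- enumerate_candidates(ct, fnames, max_order, y)
  schedule <- threshold_schedule(start, step, floor)

  used <- schedule[length(schedule)]
  rows <- minimal_only(cand[0, , drop = FALSE])
  for (thr in schedule) {
    qual <- cand[cand$consistency >= thr - EPS, , drop = FALSE]
    if (nrow(qual)) {
      used <- thr
      rows <- minimal_only(qual)
      break
    }
  }
  rows <- rows[order(-rows$coverage, rows$order, rows$formula), , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows, class = c("msc_result", "data.frame"),
            threshold = used, schedule = schedule, outcome = outcome)
}

threshold_schedule <- function(start, step, floor) {
  s <- seq(start, floor, by = -step)
  if (s[length(s)] > floor + EPS) s <- c(s, floor)
  round(s, 10)
}

# All instantiated conjunctions of order <= max_order with their
# consistency/coverage, plus a signature for subset lookups.
enumerate_candidates <- function(ct, fnames, max_order, y) {
  n_pos <- sum(y == 1L)
  lits <- literal_masks(ct, fnames)
  res <- list()
  k_max <- min(max_order, length(fnames))
  for (k in seq_len(k_max)) {
    combos <- utils::combn(fnames, k, simplify = FALSE)
    for (fs in combos) {
      grids <- expand.grid(lapply(lits[fs], names),
                           stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
      for (r in seq_len(nrow(grids))) {
        vals <- as.character(grids[r, ])
        mask <- Reduce(`&`, Map(function(f, v) lits[[f]][[v]], fs, vals))
        n_sat <- sum(mask)
        if (!n_sat) next
        n_hit <- sum(mask & y == 1L)
        res[[length(res) + 1L]] <- list(
          sig = paste(fs, vals, sep = "=", collapse = "&"),
          formula = format(conjunction(.lits = stats::setNames(vals, fs))),
          order = k,
          factors = fs, values = vals,
          consistency = n_hit / n_sat,
          coverage = if (n_pos) n_hit / n_pos else 0,
          n_satisfying = n_sat, n_positive = n_hit)
      }
    }
  }
  data.frame(
    sig = vapply(res, `[[`, "", "sig"),
    formula = vapply(res, `[[`, "", "formula"),
    order = vapply(res, `[[`, 0L, "order"),
    consistency = vapply(res, `[[`, 0, "consistency"),
    coverage = vapply(res, `[[`, 0, "coverage"),
    n_satisfying = vapply(res, `[[`, 0, "n_satisfying"),
    n_positive = vapply(res, `[[`, 0, "n_positive"),
    stringsAsFactors = FALSE
  )
}

literal_masks <- function(ct, fnames) {
  out <- list()
  for (f in fnames) {
    lv <- ct$factors[[f]]$levels
    col <- as.character(ct$data[[f]])
    out[[f]] <- stats::setNames(lapply(lv, function(v) col == v), lv)
  }
  out
}

# Keep only conjunctions none of whose proper sub-conjunctions qualify.
minimal_only <- function(qual) {
  sigs <- new.env(parent = emptyenv())
  for (s in qual$sig) assign(s, TRUE, envir = sigs)
  keep <- vapply(qual$sig, function(s) {
    parts <- strsplit(s, "&", fixed = TRUE)[[1]]
    k <- length(parts)
    if (k == 1) return(TRUE)
    for (m in seq_len(k - 1)) {
      for (sub in utils::combn(parts, m, simplify = FALSE)) {
        if (exists(paste(sub, collapse = "&"), envir = sigs)) return(FALSE)
      }
    }
    TRUE
  }, TRUE)
  qual[keep, setdiff(names(qual), "sig"), drop = FALSE]
}

#' @export
print.msc_result <- function(x, ...) {
  cat(sprintf("<msc_result> outcome '%s', consistency cutoff %.2f, %d configuration(s)\n",
              attr(x, "outcome"), attr(x, "threshold"), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(x, 20), row.names = FALSE, digits = 3)
  if (nrow(x) > 20) cat(sprintf("... %d more\n", nrow(x) - 20L))
  invisible(x)
}
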