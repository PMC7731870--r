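#' Derive binary decline outcomes from pre/during rate pairs
#'
#' For each case the relative decline is `(pre - during) / pre`; a case is
#' coded 1 for a threshold `t` exactly when the decline is `>= t`. The
#' comparison is inclusive: a facility whose rate fell by exactly 10%
#' achieves the 10%-decline outcome.
#'
#' @param pre numeric vector of pre-period rates (events per 1,000 resident
#'   days); must be strictly positive — the decline fraction is undefined at
#'   a zero baseline.
#' @param during numeric vector of intervention-period rates (same units),
#'   non-negative.
#' @param thresholds decline fractions in (0, 1), e.g. `c(0.10, 0.20)`.
#' @param names optional column names; default `declineXX` from the
#'   percentage.
#' @return a data.frame of 0/1 integer columns, one per threshold.
#' @examples
#' derive_decline_outcomes(c(3.146, 1.331), c(1.251, 1.147), c(0.10, 0.20))
#' @export
derive_decline_outcomes <- function(pre, during, thresholds, names = NULL) {
  if (length(pre) != length(during)) {
    stop_rate("`pre` and `during` must have equal length")
  }
  if (any(!is.finite(pre)) || any(pre <= 0)) {
    stop_rate("all pre-period rates must be finite and > 0")
  }
  if (any(!is.finite(during)) || any(during < 0)) {
    stop_rate("all during-period rates must be finite and >= 0")
  }
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop_usage("decline thresholds must lie in (0, 1)")
  }
  if (is.null(names)) names <- sprintf("decline%d", round(100 * thresholds))
  decline <- (pre - during) / pre
  out <- lapply(thresholds, function(t) as.integer(decline >= t - EPS))
  stats::setNames(as.data.frame(out), names)
}

#' Dichotomize a numeric series at an empirical quantile
#'
#' The cutoff is the empirical quantile with linear interpolation at rank
#' `h = (n - 1) * q + 1` on the sorted values (the R default, type 7). With
#' `direction = "low"` values at or below the cutoff are coded 1 — e.g. the
#' top-performing quartile with the lowest baseline hospitalization rates —
#' and with `direction = "high"` values above the cutoff are coded 1.
#'
#' @param x numeric series, `length(x) >= 2`.
#' @param q quantile fraction in (0, 1); default 0.25 (lowest quartile).
#' @param direction `"low"` (low values coded 1) or `"high"`.
#' @return integer 0/1 vector.
#' @examples
#' dichotomize_by_quantile(c(1, 2, 3, 4), q = 0.25) # only the 1 is coded 1
#' @export
dichotomize_by_quantile <- function(x, q = 0.25, direction = c("low", "high")) {
  direction <- match.arg(direction)
  if (length(x) < 2) stop_usage("need at least two values to dichotomize")
  if (q <= 0 || q >= 1) stop_usage("`q` must lie in (0, 1)")
  if (anyNA(x)) stop_schema("missing values in series to dichotomize")
  cutoff <- unname(stats::quantile(x, q, type = 7))
  coded <- if (direction == "low") {
    as.integer(x <= cutoff + EPS)
  } else {
    as.integer(x > cutoff + EPS)
  }
  if (all(coded == coded[1])) {
    stop_degenerate("degenerate dichotomy: every case falls on the same side of the cutoff")
  }
  coded
}

#' Dichotomize an ordinal series by a positive level set
#'
#' Codes a case 1 exactly when its value belongs to `positive_levels` — e.g.
#' collapsing an agreement scale by coding "agree" and "strongly agree" as 1
#' and "neutral"/"disagree" as 0.
#'
#' @param x character (or coercible) series.
#' @param positive_levels levels coded 1; must be a subset of `levels`.
#' @param levels the full declared level set; a value of `x` outside it is a
#'   schema violation.
#' @return integer 0/1 vector.
#' @export
dichotomize_ordinal <- function(x, positive_levels, levels) {
  x <- as.character(x)
  positive_levels <- as.character(positive_levels)
  levels <- as.character(levels)
  if (!all(positive_levels %in% levels)) {
    stop_schema("`positive_levels` must be a subset of the declared levels")
  }
  bad <- which(!x %in% levels)
  if (length(bad)) {
    stop_schema(sprintf("undeclared level '%s' at position %d", x[bad[1]], bad[1]))
  }
  as.integer(x %in% positive_levels)
}
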