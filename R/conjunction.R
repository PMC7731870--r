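#' Build a conjunction of condition literals
#'
#' A conjunction is a set of literals `factor = value` read as logical AND:
#' a case satisfies it when every literal matches the case's value. For
#' crisp factors value 1 denotes presence and 0 negation; multivalue factors
#' take one of their declared levels. At most one literal per factor;
#' conjunctions are order-free (stored sorted by factor name).
#'
#' @param ... named literals, e.g. `conjunction(support = 1, low_baseline = 0)`.
#' @param .lits alternatively, a named vector/list of literal values.
#' @return an object of class `conjunction` (named character vector).
#' @examples
#' conjunction(don_turnover = 1)
#' conjunction(support = 1, low_baseline = 0)
#' @export
conjunction <- function(..., .lits = NULL) {
  lits <- if (is.null(.lits)) list(...) else as.list(.lits)
  if (!length(lits)) stop_usage("a conjunction must contain at least one literal")
  nms <- names(lits)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop_usage("every literal must be named by its factor")
  }
  if (anyDuplicated(nms)) {
    stop_usage(sprintf("at most one literal per factor (duplicate '%s')",
                       nms[duplicated(nms)][1]))
  }
  v <- vapply(lits, function(x) as.character(x)[1], "")
  v <- v[order(names(v))]
  structure(v, class = "conjunction")
}

as_conjunction <- function(x) {
  if (inherits(x, "conjunction")) return(x)
  conjunction(.lits = x)
}

#' @export
format.conjunction <- function(x, ...) {
  lit <- ifelse(unname(x) == "1", names(x),
                ifelse(unname(x) == "0", paste0("~", names(x)),
                       paste0(names(x), "=", unname(x))))
  paste(lit, collapse = "*")
}

#' @export
print.conjunction <- function(x, ...) {
  cat("<conjunction>", format(x), "\n")
  invisible(x)
}

conj_signature <- function(conj) paste(names(conj), unname(conj),
                                       sep = "=", collapse = "&")

#' Which cases satisfy a conjunction
#'
#' @param ct a [case_table()].
#' @param conj a [conjunction()] (or named vector of literals).
#' @return logical vector over the cases of `ct`, in case order.
#' @export
satisfies <- function(ct, conj) {
  conj <- as_conjunction(conj)
  sat <- rep(TRUE, n_cases(ct))
  for (f in names(conj)) {
    decl <- ct$factors[[f]]
    if (is.null(decl) || decl$kind == "numeric") {
      stop_schema(sprintf("literal on undeclared or numeric factor '%s'", f))
    }
    val <- unname(conj[[f]])
    if (!val %in% decl$levels) {
      stop_schema(sprintf("value '%s' outside declared levels of '%s'", val, f))
    }
    sat <- sat & (as.character(ct$data[[f]]) == val)
  }
  sat
}

#' Consistency of a conjunction for an outcome
#'
#' The fraction of cases satisfying the conjunction that exhibit the
#' outcome, `n(X & Y) / n(X)`. Consistency 1 operationalizes sufficiency.
#' Undefined (an error, not 0) when no case satisfies the conjunction.
#'
#' @inheritParams satisfies
#' @param outcome name of a declared binary outcome.
#' @return a fraction in `[0, 1]`.
#' @export
consistency <- function(conj, ct, outcome) {
  y <- check_outcome(ct, outcome)
  sat <- satisfies(ct, conj)
  if (!any(sat)) {
    stop_undefined(sprintf("consistency undefined: no case satisfies %s",
                           format(as_conjunction(conj))))
  }
  sum(y[sat] == 1L) / sum(sat)
}

#' Coverage of a conjunction for an outcome
#'
#' The fraction of outcome-exhibiting cases that satisfy the conjunction,
#' `n(X & Y) / n(Y)`. Coverage 1 operationalizes necessity. Undefined when
#' no case exhibits the outcome.
#'
#' @inheritParams consistency
#' @return a fraction in `[0, 1]`.
#' @export
coverage <- function(conj, ct, outcome) {
  y <- check_outcome(ct, outcome)
  if (!any(y == 1L)) {
    stop_undefined(sprintf("coverage undefined: no case exhibits outcome '%s'",
                           outcome))
  }
  sat <- satisfies(ct, conj)
  sum(sat & y == 1L) / sum(y == 1L)
}

#' Assess a condition as necessary and/or sufficient for an outcome
#'
#' A condition is sufficient when every case satisfying it exhibits the
#' outcome (consistency 1) and necessary when every outcome case satisfies
#' it (coverage 1).
#'
#' @inheritParams consistency
#' @return list with `sufficient`, `necessary`, and the underlying counts
#'   (`n_satisfying`, `n_satisfying_positive`, `n_outcome`).
#' @examples
#' ct <- optimistic_facilities()
#' assess_necessity_sufficiency(conjunction(don_turnover = 1), ct, "decline10")
#' @export
assess_necessity_sufficiency <- function(conj, ct, outcome) {
  conj <- as_conjunction(conj)
  y <- check_outcome(ct, outcome)
  sat <- satisfies(ct, conj)
  if (!any(sat)) stop_undefined("condition satisfied by no case")
  if (!any(y == 1L)) stop_undefined("no outcome-positive case")
  n_sat <- sum(sat)
  n_pos <- sum(sat & y == 1L)
  n_out <- sum(y == 1L)
  list(
    condition = format(conj),
    sufficient = n_pos == n_sat,
    necessary = n_pos == n_out,
    consistency = n_pos / n_sat,
    coverage = n_pos / n_out,
    n_satisfying = n_sat,
    n_satisfying_positive = n_pos,
    n_outcome = n_out
  )
}
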