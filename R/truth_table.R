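#' Build a truth table over a crisp factor subset
#'
#' Groups the cases by their exact configuration over the chosen crisp
#' factors. Each observed row carries its member cases, size, count of
#' outcome-positive cases and row consistency, and is assigned an output:
#' 1 when its consistency meets `threshold`, otherwise 0. A contradictory
#' row (some but not all members positive, below threshold) is output 0 —
#' it is observed evidence against sufficiency, never a don't-care.
#' Configurations observed in no case are listed as remainders (output
#' `NA`), available as don't-cares to parsimonious minimization.
#'
#' @param ct a [case_table()].
#' @param factors non-empty character vector of crisp factor names.
#' @param outcome a declared binary outcome.
#' @param threshold row-consistency threshold in (0, 1] (default 1).
#' @return a `truth_table`: data.frame with one 0/1 column per factor, then
#'   `n`, `positives`, `consistency`, `output` (1/0/`NA` for remainder) and
#'   a list-column `cases` of member case ids; attributes `factors`,
#'   `outcome`, `threshold`.
#' @examples
#' ct <- optimistic_facilities()
#' build_truth_table(ct, c("don_turnover", "support", "low_baseline"), "decline10")
#' @export
build_truth_table <- function(ct, factors, outcome, threshold = 1) {
  y <- check_outcome(ct, outcome)
  if (!length(factors)) stop_usage("`factors` must be non-empty")
  if (threshold <= 0 || threshold > 1) stop_usage("`threshold` must lie in (0, 1]")
  for (f in factors) {
    decl <- ct$factors[[f]]
    if (is.null(decl)) stop_schema(sprintf("undeclared factor '%s'", f))
    if (decl$kind != "crisp") {
      stop_schema(sprintf(
        "factor '%s' is %s; dichotomize it before building a truth table",
        f, decl$kind))
    }
  }
  k <- length(factors)
  grid <- expand.grid(rep(list(c(0L, 1L)), k), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- factors

  conf <- as.matrix(ct$data[, factors, drop = FALSE])
  key_case <- apply(conf, 1, paste, collapse = "")
  key_row <- apply(as.matrix(grid), 1, paste, collapse = "")

  n <- positives <- integer(nrow(grid))
  cases <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    m <- key_case == key_row[i]
    n[i] <- sum(m)
    positives[i] <- sum(y[m] == 1L)
    cases[[i]] <- ct$case_ids[m]
  }
  consistency <- ifelse(n > 0, positives / n, NA_real_)
  output <- ifelse(n == 0, NA_integer_,
                   as.integer(consistency >= threshold - EPS))

  tt <- cbind(grid,
              data.frame(n = n, positives = positives,
                         consistency = consistency, output = output))
  tt$cases <- cases
  structure(tt, class = c("truth_table", "data.frame"),
            factors = factors, outcome = outcome, threshold = threshold)
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("<truth_table> %s ~ %s, row-consistency threshold %.2f\n",
              attr(x, "outcome"), paste(attr(x, "factors"), collapse = "*"),
              attr(x, "threshold")))
  df <- as.data.frame(x)
  df$cases <- vapply(df$cases, paste, "", collapse = ",")
  df$output[is.na(df$output)] <- NA
  print(df, row.names = FALSE, digits = 3)
  invisible(x)
}

tt_config_matrix <- function(tt, which = c("on", "off", "dc")) {
  which <- match.arg(which)
  sel <- switch(which,
                on = !is.na(tt$output) & tt$output == 1L,
                off = !is.na(tt$output) & tt$output == 0L,
                dc = is.na(tt$output))
  as.matrix(as.data.frame(tt)[sel, attr(tt, "factors"), drop = FALSE])
}
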