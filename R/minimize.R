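#' Construct a DNF solution model
#'
#' A disjunction of conjunctions ("solution paths"): a case satisfies the
#' model when it satisfies at least one term. Terms with a literal-subset
#' relation are redundant; the more specific term is dropped at
#' construction. Terms are stored in a deterministic order (more literals
#' first, then alphabetically by formula); [model_metrics()] reorders paths
#' by raw coverage for presentation.
#'
#' @param terms list of [conjunction()]s.
#' @param strategy `"parsimonious"` or `"conservative"` tag.
#' @param outcome optional outcome name the model explains.
#' @return an object of class `dnf_model`.
#' @export
dnf_model <- function(terms, strategy = "parsimonious", outcome = NULL) {
  if (!length(terms)) stop_usage("a model needs at least one term")
  terms <- lapply(terms, as_conjunction)
  # drop terms subsumed by (i.e. literal-supersets of) another term
  keep <- rep(TRUE, length(terms))
  for (i in seq_along(terms)) {
    for (j in seq_along(terms)) {
      if (i == j || !keep[j]) next
      a <- terms[[j]]; b <- terms[[i]]
      if (length(a) < length(b) &&
          all(names(a) %in% names(b)) &&
          all(unname(a) == unname(b[names(a)]))) {
        keep[i] <- FALSE
        break
      }
    }
  }
  terms <- terms[keep]
  sig <- vapply(terms, conj_signature, "")
  terms <- terms[!duplicated(sig)]
  terms <- terms[order(-lengths(terms), vapply(terms, format, ""))]
  structure(list(terms = terms, strategy = strategy, outcome = outcome),
            class = "dnf_model")
}

model_signature <- function(model) {
  paste(sort(vapply(model$terms, conj_signature, "")), collapse = " | ")
}

#' Factors used by a model
#' @param model a `dnf_model`.
#' @return character vector of factor names appearing in any term.
#' @export
model_factors <- function(model) {
  sort(unique(unlist(lapply(model$terms, names))))
}

#' @export
format.dnf_model <- function(x, ...) {
  f <- paste(vapply(x$terms, format, ""), collapse = " + ")
  if (!is.null(x$outcome)) paste(f, "->", x$outcome) else f
}

#' @export
print.dnf_model <- function(x, ...) {
  cat(sprintf("<dnf_model> [%s] %s\n", x$strategy, format(x)))
  invisible(x)
}

#' Which cases satisfy a model
#' @param ct a [case_table()].
#' @param model a `dnf_model`.
#' @return logical vector over cases.
#' @export
satisfies_model <- function(ct, model) {
  Reduce(`|`, lapply(model$terms, function(tm) satisfies(ct, tm)))
}

#' Logical equivalence of two DNF models
#'
#' Evaluates both models on every configuration of the given crisp factors
#' and reports whether they agree everywhere.
#'
#' @param a,b `dnf_model` objects (or lists of conjunctions).
#' @param factors crisp factor names spanning the configuration space;
#'   default the union of factors used by `a` and `b`.
#' @return `TRUE`/`FALSE`.
#' @export
dnf_equivalent <- function(a, b, factors = NULL) {
  if (!inherits(a, "dnf_model")) a <- dnf_model(a)
  if (!inherits(b, "dnf_model")) b <- dnf_model(b)
  factors <- factors %||% sort(unique(c(model_factors(a), model_factors(b))))
  grid <- expand.grid(rep(list(0:1), length(factors)), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- factors
  identical(eval_dnf_on_grid(a, grid), eval_dnf_on_grid(b, grid))
}

eval_dnf_on_grid <- function(model, grid) {
  hit <- rep(FALSE, nrow(grid))
  for (tm in model$terms) {
    m <- rep(TRUE, nrow(grid))
    for (f in names(tm)) m <- m & (grid[[f]] == as.integer(tm[[f]]))
    hit <- hit | m
  }
  hit
}

#' Minimize a truth table into its minimal DNF solutions
#'
#' Classic two-level Boolean minimization of the output-1 rows. Prime
#' implicants are grown by iterated merging of adjacent implicants
#' (Quine-McCluskey); under the `"parsimonious"` strategy remainder rows
#' (unobserved configurations) are usable as don't-cares, under
#' `"conservative"` only output-1 rows may be merged, so no solution term
#' ever implies an unobserved configuration. All irredundant covers of the
#' output-1 rows are then enumerated (Petrick's method) and the minimal
#' ones — fewest terms, then fewest total literals — are returned, one
#' `dnf_model` each. More than one returned model is model ambiguity.
#'
#' @param tt a [build_truth_table()] result.
#' @param strategy `"parsimonious"` (default) or `"conservative"`.
#' @return list of `dnf_model` objects, deterministically ordered, with
#'   attribute `ambiguous`.
#' @examples
#' ct <- optimistic_facilities()
#' tt <- build_truth_table(ct, c("don_turnover", "support", "low_baseline"),
#'                         "decline10")
#' minimize(tt)
#' @export
minimize <- function(tt, strategy = c("parsimonious", "conservative")) {
  strategy <- match.arg(strategy)
  factors <- attr(tt, "factors")
  on <- tt_config_matrix(tt, "on")
  if (!nrow(on)) stop_no_model("no output-1 row in the truth table")
  dc <- if (strategy == "parsimonious") tt_config_matrix(tt, "dc") else
    matrix(integer(), 0, length(factors), dimnames = list(NULL, factors))

  primes <- qm_primes(rbind(on, dc))
  covm <- covers_matrix(primes, on)          # primes x on-minterms
  covers <- petrick_min_covers(covm, primes)

  models <- lapply(covers, function(idx) {
    terms <- lapply(idx, function(i) implicant_to_conjunction(primes[i, ], factors))
    dnf_model(terms, strategy = strategy, outcome = attr(tt, "outcome"))
  })
  models <- models[!duplicated(vapply(models, model_signature, ""))]
  models <- models[order(vapply(models, model_signature, ""))]
  structure(models, ambiguous = length(models) > 1)
}

# Quine-McCluskey prime implicants. Implicants are integer vectors over the
# factors with NA marking an eliminated ("dash") position.
qm_primes <- function(minterms) {
  cur <- unique(minterms)
  storage.mode(cur) <- "integer"
  primes <- NULL
  while (nrow(cur)) {
    used <- rep(FALSE, nrow(cur))
    nxt <- NULL
    if (nrow(cur) > 1) {
      napat <- apply(is.na(cur), 1, paste, collapse = "")
      for (i in seq_len(nrow(cur) - 1)) {
        for (j in (i + 1):nrow(cur)) {
          if (napat[i] != napat[j]) next
          d <- which(cur[i, ] != cur[j, ])
          if (length(d) == 1) {
            m <- cur[i, ]
            m[d] <- NA_integer_
            nxt <- rbind(nxt, m)
            used[i] <- used[j] <- TRUE
          }
        }
      }
    }
    primes <- rbind(primes, cur[!used, , drop = FALSE])
    cur <- if (is.null(nxt)) {
      matrix(integer(), 0, ncol(minterms))
    } else {
      unique(nxt, MARGIN = 1)
    }
  }
  rownames(primes) <- NULL
  unique(primes, MARGIN = 1)
}

covers_matrix <- function(primes, on) {
  out <- matrix(FALSE, nrow(primes), nrow(on))
  for (i in seq_len(nrow(primes))) {
    p <- primes[i, ]
    for (j in seq_len(nrow(on))) {
      out[i, j] <- all(is.na(p) | p == on[j, ])
    }
  }
  out
}

# Petrick's method: expand the product of per-minterm clauses into its
# irredundant sums-of-primes, with absorption after every clause, then keep
# the covers minimal by term count and total literal count.
petrick_min_covers <- function(covm, primes) {
  n_lit <- apply(primes, 1, function(p) sum(!is.na(p)))
  prods <- list(integer(0))
  for (m in seq_len(ncol(covm))) {
    clause <- which(covm[, m])
    new <- list()
    for (p in prods) {
      if (any(clause %in% p)) {
        new[[length(new) + 1L]] <- p        # clause already satisfied
      } else {
        for (q in clause) new[[length(new) + 1L]] <- sort(c(p, q))
      }
    }
    prods <- absorb(unique(new))
  }
  sizes <- lengths(prods)
  prods <- prods[sizes == min(sizes)]
  lits <- vapply(prods, function(p) sum(n_lit[p]), 0)
  prods[lits == min(lits)]
}

absorb <- function(prods) {
  if (length(prods) < 2) return(prods)
  ord <- order(lengths(prods))
  prods <- prods[ord]
  keep <- rep(TRUE, length(prods))
  for (i in seq_along(prods)) {
    if (!keep[i]) next
    for (j in seq_along(prods)) {
      if (j >= i) break
      if (keep[j] && all(prods[[j]] %in% prods[[i]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  prods[keep]
}

implicant_to_conjunction <- function(imp, factors) {
  sel <- !is.na(imp)
  if (!any(sel)) {
    stop_degenerate("minimization produced the empty (tautological) term")
  }
  conjunction(.lits = stats::setNames(as.integer(imp[sel]), factors[sel]))
}
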