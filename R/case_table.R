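#' Declare an analysis factor
#'
#' A factor declaration names one column of a case table and states its kind:
#' `"crisp"` (binary 0/1 condition), `"multivalue"` (categorical condition
#' with a declared level set), or `"numeric"` (raw numeric column such as a
#' hospitalization rate, carried for outcome derivation or dichotomization
#' but not usable directly as a condition).
#'
#' @param name column name.
#' @param kind one of `"crisp"`, `"multivalue"`, `"numeric"`.
#' @param levels level set for multivalue factors (character); ignored for
#'   crisp (always `c(0, 1)`) and numeric factors.
#' @return a `factor_decl` list.
#' @export
factor_decl <- function(name, kind = c("crisp", "multivalue", "numeric"),
                        levels = NULL) {
  kind <- match.arg(kind)
  if (kind == "multivalue") {
    if (is.null(levels) || length(levels) < 2) {
      stop_schema(sprintf("multivalue factor '%s' needs >= 2 declared levels", name))
    }
    levels <- as.character(levels)
  }
  if (kind == "crisp") levels <- c("0", "1")
  structure(list(name = name, kind = kind, levels = levels),
            class = "factor_decl")
}

#' Build a validated case table
#'
#' The universal analysis input: one row per case, columns for declared
#' condition factors and for binary outcomes. Validation is strict — a
#' missing cell, an undeclared level, a non-0/1 value in a crisp column or a
#' duplicate case id is an error, never silently repaired.
#'
#' @param data a data.frame holding one row per case.
#' @param factors list of [factor_decl()] declarations (or a named character
#'   vector of kinds for all-crisp tables, e.g. `c(don_turnover = "crisp")`).
#' @param outcomes character vector of binary outcome column names.
#' @param id_col name of the case-id column in `data`.
#' @return an object of class `case_table`.
#' @examples
#' ct <- case_table(
#'   data.frame(id = c("a", "b"), x = c(1, 0), y = c(0, 1), out = c(1, 0)),
#'   factors = list(factor_decl("x"), factor_decl("y")),
#'   outcomes = "out", id_col = "id"
#' )
#' @export
case_table <- function(data, factors, outcomes = character(), id_col = "case_id") {
  if (!is.data.frame(data)) stop_schema("`data` must be a data.frame")
  factors <- normalize_factor_decls(factors)
  fnames <- vapply(factors, `[[`, "", "name")
  if (anyDuplicated(fnames)) stop_schema("duplicate factor declarations")
  if (!id_col %in% names(data)) {
    stop_schema(sprintf("missing case-id column '%s'", id_col))
  }
  need <- c(fnames, outcomes)
  absent <- setdiff(need, names(data))
  if (length(absent)) {
    stop_schema(sprintf("missing column(s): %s", paste(absent, collapse = ", ")))
  }

  ids <- as.character(data[[id_col]])
  if (anyDuplicated(ids)) {
    stop_schema(sprintf("duplicate case id '%s'", ids[duplicated(ids)][1]))
  }

  out <- data.frame(row.names = NULL)
  if (nrow(data)) out <- data[, FALSE, drop = FALSE]
  for (fd in factors) {
    v <- data[[fd$name]]
    if (anyNA(v)) {
      stop_schema(sprintf("missing cell in column '%s' (case %s)",
                          fd$name, ids[which(is.na(v))[1]]))
    }
    if (fd$kind == "numeric") {
      out[[fd$name]] <- as.numeric(v)
      next
    }
    vc <- as.character(v)
    bad <- which(!vc %in% fd$levels)
    if (length(bad)) {
      stop_schema(sprintf(
        "value '%s' outside declared levels of factor '%s' (case %s)",
        vc[bad[1]], fd$name, ids[bad[1]]))
    }
    out[[fd$name]] <- if (fd$kind == "crisp") as.integer(vc) else vc
  }
  for (oc in outcomes) {
    v <- data[[oc]]
    if (anyNA(v)) {
      stop_schema(sprintf("missing cell in outcome '%s' (case %s)",
                          oc, ids[which(is.na(v))[1]]))
    }
    vi <- suppressWarnings(as.integer(as.character(v)))
    if (anyNA(vi) || !all(vi %in% c(0L, 1L))) {
      stop_schema(sprintf("outcome '%s' must be binary 0/1", oc))
    }
    out[[oc]] <- vi
  }

  structure(
    list(data = out, case_ids = ids,
         factors = stats::setNames(factors, fnames),
         outcomes = outcomes),
    class = "case_table")
}

normalize_factor_decls <- function(factors) {
  if (inherits(factors, "factor_decl")) factors <- list(factors)
  if (is.character(factors)) {
    factors <- mapply(function(n, k) factor_decl(n, k),
                      names(factors), unname(factors), SIMPLIFY = FALSE)
  }
  if (!is.list(factors) || !length(factors) ||
      !all(vapply(factors, inherits, TRUE, "factor_decl"))) {
    stop_schema("`factors` must be a list of factor_decl objects")
  }
  factors
}

#' @export
print.case_table <- function(x, ...) {
  kinds <- vapply(x$factors, `[[`, "", "kind")
  cat(sprintf("<case_table> %d cases, %d factors (%d crisp, %d multivalue, %d numeric), %d outcome(s)\n",
              n_cases(x), length(x$factors),
              sum(kinds == "crisp"), sum(kinds == "multivalue"),
              sum(kinds == "numeric"), length(x$outcomes)))
  if (n_cases(x)) {
    df <- cbind(case_id = x$case_ids, x$data)
    print(utils::head(df, 10), row.names = FALSE)
    if (n_cases(x) > 10) cat(sprintf("... %d more cases\n", n_cases(x) - 10L))
  }
  invisible(x)
}

#' Number of cases in a case table
#' @param ct a `case_table`.
#' @return integer case count.
#' @export
n_cases <- function(ct) length(ct$case_ids)

condition_factor_names <- function(ct, kinds = c("crisp", "multivalue")) {
  fk <- vapply(ct$factors, `[[`, "", "kind")
  names(fk)[fk %in% kinds]
}

check_outcome <- function(ct, outcome) {
  if (!outcome %in% ct$outcomes) {
    stop_schema(sprintf("undeclared outcome '%s'", outcome))
  }
  ct$data[[outcome]]
}

#' Read a case table from delimited text plus a factor schema
#'
#' The schema declares, for every analysis column, its role and (for
#' multivalue factors) its level set, so that validation can reject
#' out-of-domain cells at load time. Schemas are JSON or YAML files (or an
#' equivalent R list) of the form:
#'
#' ```yaml
#' id: facility_id
#' factors:
#'   don_turnover: {kind: crisp}
#'   star_rating:  {kind: multivalue, levels: ["1","2","3","4","5"]}
#'   pre_rate:     {kind: numeric}
#' outcomes: [decline10, decline20]
#' ```
#'
#' @param path CSV file with a header row.
#' @param schema path to a JSON/YAML schema file, or a list with elements
#'   `id`, `factors`, `outcomes` as above.
#' @param sep field separator (default comma).
#' @return a [case_table()].
#' @export
load_case_table <- function(path, schema, sep = ",") {
  schema <- read_schema(schema)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  decls <- mapply(function(n, d) {
    factor_decl(n, d$kind %||% "crisp", d$levels)
  }, names(schema$factors), schema$factors, SIMPLIFY = FALSE)
  case_table(df, decls, outcomes = schema$outcomes %||% character(),
             id_col = schema$id %||% "case_id")
}

read_schema <- function(schema) {
  if (is.character(schema) && length(schema) == 1) {
    schema <- if (grepl("\\.ya?ml$", schema, ignore.case = TRUE)) {
      yaml::read_yaml(schema)
    } else {
      jsonlite::fromJSON(schema, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    }
  }
  if (!is.list(schema) || is.null(schema$factors)) {
    stop_schema("schema must declare a `factors` block")
  }
  schema
}

#' Write a case table to CSV
#'
#' @param ct a `case_table`.
#' @param path output file.
#' @param id_col name for the case-id column.
#' @return `path`, invisibly.
#' @export
write_case_table <- function(ct, path, id_col = "case_id") {
  df <- cbind(stats::setNames(data.frame(ct$case_ids), id_col), ct$data)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
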