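# Independent brute-force oracles and random-table builders used by the
# property tests. Everything here works directly on plain data.frames so
# the oracles share no code path with the package implementation.

# Random all-crisp case table with one binary outcome.
random_crisp_table <- function(n_cases, n_factors, p_outcome = 0.5) {
  fnames <- sprintf("F%d", seq_len(n_factors))
  df <- as.data.frame(lapply(fnames, function(f) {
    sample(0:1, n_cases, replace = TRUE)
  }))
  names(df) <- fnames
  df$case_id <- sprintf("c%d", seq_len(n_cases))
  df$Y <- stats::rbinom(n_cases, 1, p_outcome)
  case_table(df, stats::setNames(rep("crisp", n_factors), fnames),
             outcomes = "Y", id_col = "case_id")
}

# Brute-force minimally-sufficient-condition search: enumerate every value
# assignment over every factor subset of size <= max_order by hand, compute
# consistency/coverage by counting rows, walk the threshold schedule, and
# keep assignments none of whose proper sub-assignments qualify.
oracle_msc <- function(df, fnames, yname, max_order, start = 1,
                       step = 0.05, floor = 0.5) {
  y <- df[[yname]]
  n_pos <- sum(y == 1)
  cand <- list()
  for (k in seq_len(min(max_order, length(fnames)))) {
    for (fs in utils::combn(fnames, k, simplify = FALSE)) {
      vals <- expand.grid(rep(list(0:1), k))
      for (r in seq_len(nrow(vals))) {
        v <- as.integer(vals[r, ])
        hit <- rep(TRUE, nrow(df))
        for (i in seq_len(k)) hit <- hit & df[[fs[i]]] == v[i]
        if (!any(hit)) next
        cand[[length(cand) + 1L]] <- list(
          factors = fs, values = v,
          key = paste(fs, v, sep = "=", collapse = "&"),
          cons = sum(hit & y == 1) / sum(hit),
          cov = if (n_pos) sum(hit & y == 1) / n_pos else 0,
          n_sat = sum(hit), n_hit = sum(hit & y == 1))
      }
    }
  }
  sched <- seq(start, floor, by = -step)
  if (sched[length(sched)] > floor + 1e-9) sched <- c(sched, floor)
  for (thr in sched) {
    qual <- Filter(function(cc) cc$cons >= thr - 1e-9, cand)
    if (!length(qual)) next
    keys <- vapply(qual, `[[`, "", "key")
    minimal <- Filter(function(cc) {
      k <- length(cc$factors)
      if (k == 1) return(TRUE)
      for (m in seq_len(k - 1)) {
        for (idx in utils::combn(seq_len(k), m, simplify = FALSE)) {
          sub <- paste(cc$factors[idx], cc$values[idx], sep = "=",
                       collapse = "&")
          if (sub %in% keys) return(FALSE)
        }
      }
      TRUE
    }, qual)
    out <- data.frame(
      key = vapply(minimal, `[[`, "", "key"),
      order = vapply(minimal, function(cc) length(cc$factors), 0L),
      cons = vapply(minimal, `[[`, 0, "cons"),
      cov = vapply(minimal, `[[`, 0, "cov"),
      stringsAsFactors = FALSE)
    return(list(threshold = thr, rows = out))
  }
  list(threshold = sched[length(sched)],
       rows = data.frame(key = character(), order = integer(),
                         cons = numeric(), cov = numeric()))
}

# canonical signature of a package msc_result row, for oracle comparison
msc_result_keys <- function(msc) {
  vapply(msc$formula, function(f) {
    lits <- strsplit(f, "*", fixed = TRUE)[[1]]
    fac <- sub("^~", "", lits)
    val <- ifelse(grepl("^~", lits), 0L, 1L)
    o <- order(fac)
    paste(fac[o], val[o], sep = "=", collapse = "&")
  }, "", USE.NAMES = FALSE)
}

# Hand evaluation of a dnf_model term list on a 0/1 configuration row.
oracle_eval_model <- function(model, config) {
  any(vapply(model$terms, function(tm) {
    all(vapply(names(tm), function(f) {
      config[[f]] == as.integer(tm[[f]])
    }, TRUE))
  }, TRUE))
}

table2_fixture <- function() optimistic_facilities()

fix10_subset <- c("don_turnover", "support", "low_baseline")
fix20_subset <- c("don_turnover", "support", "low_baseline", "chess")
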