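# Independent reference interpreter: evaluates one row at a time with
# explicit three-valued truth tables, sorts with an explicit tie-break
# index, truncates after sorting.  Used to cross-check run_query; it
# deliberately shares no code with the engine's vectorized evaluator.

oracle_eval <- function(node, row) {
  switch(node$type,
    num = node$value,
    col = {
      v <- row[[node$name]]
      if (is.null(v) || length(v) != 1L || is.na(v) || !is.finite(v)) NA_real_
      else as.numeric(v)
    },
    neg = {
      v <- oracle_eval(node$child, row)
      if (is.na(v)) NA_real_ else -v
    },
    arith = {
      l <- oracle_eval(node$lhs, row)
      r <- oracle_eval(node$rhs, row)
      if (is.na(l) || is.na(r)) return(NA_real_)
      v <- switch(node$op,
                  "+" = l + r, "-" = l - r, "*" = l * r,
                  "/" = if (r == 0) NA_real_ else l / r)
      if (is.na(v) || !is.finite(v)) NA_real_ else v
    },
    cmp = {
      l <- oracle_eval(node$lhs, row)
      r <- oracle_eval(node$rhs, row)
      if (is.na(l) || is.na(r)) return(NA)
      switch(node$op,
             ">" = l > r, "<" = l < r, ">=" = l >= r, "<=" = l <= r,
             "=" = l == r, "!=" = l != r)
    },
    find = {
      cell <- row[[node$column]]
      if (is.null(cell) || length(cell) != 1L || is.na(cell)) return(FALSE)
      grepl(tolower(node$needle), tolower(cell), fixed = TRUE)
    },
    not = {
      v <- oracle_eval(node$child, row)
      if (is.na(v)) NA else !v
    },
    and = {
      l <- oracle_eval(node$lhs, row)
      r <- oracle_eval(node$rhs, row)
      if (identical(l, FALSE) || identical(r, FALSE)) FALSE
      else if (is.na(l) || is.na(r)) NA
      else TRUE
    },
    or = {
      l <- oracle_eval(node$lhs, row)
      r <- oracle_eval(node$rhs, row)
      if (identical(l, TRUE) || identical(r, TRUE)) TRUE
      else if (is.na(l) || is.na(r)) NA
      else FALSE
    },
    stop("oracle: unknown node type ", node$type))
}

# Naive full-query evaluation over a joined_table.  Returns the row
# data frame (with appended sorter values) plus the matched count.
oracle_run_query <- function(table, filter_text = "", sorter_text = "",
                             maxrows = 0L, descending = TRUE) {
  df <- table$data
  rows <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  keep <- integer(0)
  if (nzchar(trimws(filter_text))) {
    fnode <- parse_filter(filter_text)
    for (i in seq_along(rows)) {
      if (identical(oracle_eval(fnode, rows[[i]]), TRUE)) keep <- c(keep, i)
    }
  } else {
    keep <- seq_along(rows)
  }
  matched <- length(keep)
  out <- df[keep, , drop = FALSE]
  if (nzchar(trimws(sorter_text))) {
    snode <- parse_sorter(sorter_text)
    vals <- vapply(keep, function(i) oracle_eval(snode, rows[[i]]), numeric(1))
    sortkey <- ifelse(is.na(vals), 0, if (descending) -vals else vals)
    ord <- order(is.na(vals), sortkey, seq_along(vals))
    out <- out[ord, , drop = FALSE]
    out$sorter_value <- vals[ord]
  }
  if (maxrows > 0L && nrow(out) > maxrows)
    out <- out[seq_len(maxrows), , drop = FALSE]
  rownames(out) <- NULL
  list(rows = out, matched = matched)
}
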