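# Query evaluation.  Numeric evaluation follows three-valued logic:
# a missing cell or a division by zero makes the value undefined (NA),
# comparisons on undefined operands are undefined, and AND/OR/NOT use
# Kleene semantics (NA OR TRUE is TRUE, NA AND FALSE is FALSE).  find()
# is two-valued: text search over an absent annotation is a definite
# non-match.  A row is selected iff its filter value is definitely TRUE.

#' Construct a query specification
#'
#' A query is three independent parameters: a boolean FILTER selecting
#' rows, a numeric SORTER computed per matching row (appended as the
#' last result column and used for ordering), and MAXROWS truncating
#' the sorted result.
#'
#' @param filter filter expression text; `""` matches every row.
#' @param sorter sorter expression text; `""` keeps input order and
#'   omits the sorter column.
#' @param maxrows non-negative row limit applied after sorting;
#'   `0` means unlimited.
#' @param descending sort direction; `TRUE` (default) puts the largest
#'   sorter values first, `FALSE` is the "inverted" sorter that
#'   surfaces the smallest values first.
#' @return a `query_spec` object.
#' @export
query_spec <- function(filter = "", sorter = "", maxrows = 0L,
                       descending = TRUE) {
  if (length(maxrows) != 1L || is.na(maxrows) || maxrows < 0 ||
      maxrows != as.integer(maxrows))
    xq_input_error("maxrows must be a single non-negative integer")
  if (is.null(filter) || is.na(filter)) filter <- ""
  if (is.null(sorter) || is.na(sorter)) sorter <- ""
  if (nzchar(trimws(filter))) parse_filter(filter)   # fail fast on bad text
  if (nzchar(trimws(sorter))) parse_sorter(sorter)
  structure(list(filter = filter, sorter = sorter,
                 maxrows = as.integer(maxrows),
                 descending = isTRUE(descending)),
            class = "query_spec")
}

#' @export
print.query_spec <- function(x, ...) {
  cat("<query_spec>\n")
  cat("  FILTER:  ", if (nzchar(x$filter)) x$filter else "(all rows)", "\n")
  cat("  SORTER:  ", if (nzchar(x$sorter)) x$sorter else "(input order)", "\n")
  cat("  MAXROWS: ", if (x$maxrows > 0) x$maxrows else "unlimited",
      if (x$descending) " (descending)" else " (ascending)", "\n")
  invisible(x)
}

# Vectorized evaluator over the columns of a data frame.  Numeric nodes
# return a double vector (NA = undefined); boolean nodes a logical
# vector (NA = undefined, except find which never returns NA).
eval_node <- function(node, data) {
  n <- nrow(data)
  switch(node$type,
    num = rep(node$value, n),
    col = {
      v <- data[[node$name]]
      v[!is.finite(v)] <- NA_real_
      v
    },
    find = {
      cell <- data[[node$column]]
      out <- grepl(tolower(node$needle), tolower(as.character(cell)),
                   fixed = TRUE)
      out[is.na(cell)] <- FALSE
      out
    },
    neg = -eval_node(node$child, data),
    arith = {
      l <- eval_node(node$lhs, data)
      r <- eval_node(node$rhs, data)
      v <- switch(node$op, "+" = l + r, "-" = l - r, "*" = l * r, "/" = l / r)
      v[!is.finite(v)] <- NA_real_   # division by zero etc. is undefined
      v
    },
    cmp = {
      l <- eval_node(node$lhs, data)
      r <- eval_node(node$rhs, data)
      switch(node$op,
             ">" = l > r, "<" = l < r, ">=" = l >= r, "<=" = l <= r,
             "=" = l == r, "!=" = l != r)
    },
    not = !eval_node(node$child, data),
    and = eval_node(node$lhs, data) & eval_node(node$rhs, data),
    or  = eval_node(node$lhs, data) | eval_node(node$rhs, data),
    xq_input_error(sprintf("unknown node type '%s'", node$type)))
}

as_record_frame <- function(row) {
  if (is.data.frame(row)) {
    if (nrow(row) != 1L) xq_input_error("expected a single record")
    row
  } else {
    as.data.frame(lapply(row, function(x) if (is.null(x)) NA else x),
                  stringsAsFactors = FALSE, check.names = FALSE)
  }
}

#' Evaluate a numeric expression on one record
#'
#' @param row named list or one-row data frame.
#' @param node numeric-kind expression node (or expression text).
#' @return a number, or `NA` when undefined (missing operand cell or
#'   division by zero).
#' @export
eval_numeric <- function(row, node) {
  if (is.character(node)) node <- parse_sorter(node)
  if (node_kind(node) != "num") xq_input_error("node is not numeric-valued")
  as.numeric(eval_node(node, as_record_frame(row)))
}

#' Evaluate a boolean expression on one record
#'
#' @param row named list or one-row data frame.
#' @param node boolean-kind expression node (or expression text).
#' @return `TRUE`, `FALSE`, or `NA` (undefined under three-valued
#'   logic); rows are only ever selected on `TRUE`.
#' @export
eval_boolean <- function(row, node) {
  if (is.character(node)) node <- parse_filter(node)
  if (node_kind(node) != "bool") xq_input_error("node is not boolean-valued")
  as.logical(eval_node(node, as_record_frame(row)))
}

#' Evaluate a find() predicate on one record
#'
#' Case-insensitive substring containment of the needle in the row's
#' annotation cell text; a missing or empty cell is a definite
#' non-match (`FALSE`, never `NA`).
#'
#' @param row named list or one-row data frame.
#' @param call a `find` expression node.
#' @return `TRUE` or `FALSE`.
#' @export
eval_find <- function(row, call) {
  if (!inherits(call, "xq_node") || call$type != "find")
    xq_input_error("`call` must be a find() node")
  as.logical(eval_node(call, as_record_frame(row)))
}

# Name for the appended sorter column, avoiding collisions.
sorter_column_name <- function(existing) {
  name <- "sorter_value"
  while (name %in% existing) name <- paste0(name, "_")
  name
}

#' Run a query against a joined table
#'
#' Executes filter, sorter and truncation in SQL order: rows where the
#' filter is definitely true are kept, the sorter value is computed per
#' matching row and appended as the last column, rows are sorted by it
#' (stable; ties keep input order; undefined sorter values sort last),
#' and MAXROWS truncation is applied after sorting.
#'
#' @param table a `joined_table` (see [join_datasets()],
#'   [as_joined_table()]).
#' @param query a [query_spec()].
#' @return a `result_table`: fields `columns`, `rows` (data frame),
#'   `matched` (rows passing the filter, before truncation),
#'   `total_scanned`, `sorter_column` (name of the appended column, or
#'   `NULL` when the sorter was empty), `key_column`,
#'   `numeric_columns`, `annotation_columns`.
#' @export
run_query <- function(table, query) {
  stopifnot(inherits(table, "joined_table"))
  if (!inherits(query, "query_spec")) xq_input_error("`query` must be a query_spec")

  filter_node <- if (nzchar(trimws(query$filter))) parse_filter(query$filter)
  sorter_node <- if (nzchar(trimws(query$sorter))) parse_sorter(query$sorter)
  findings <- character(0)
  if (!is.null(filter_node)) findings <- c(findings, validate_columns(filter_node, table))
  if (!is.null(sorter_node)) findings <- c(findings, validate_columns(sorter_node, table))
  if (length(findings))
    xq_validation_error(sprintf("unknown or mis-typed columns: %s",
                                paste(unique(findings), collapse = "; ")))

  data <- table$data
  n <- nrow(data)
  if (is.null(filter_node)) {
    sel <- seq_len(n)
  } else {
    mask <- eval_node(filter_node, data)
    sel <- which(!is.na(mask) & mask)
  }
  matched <- length(sel)

  rows <- data[sel, , drop = FALSE]
  sorter_column <- NULL
  numeric_columns <- table$numeric_columns
  if (!is.null(sorter_node)) {
    values <- as.numeric(eval_node(sorter_node, rows))
    ord <- order(values, decreasing = query$descending,
                 na.last = TRUE, method = "radix")
    rows <- rows[ord, , drop = FALSE]
    sorter_column <- sorter_column_name(names(rows))
    rows[[sorter_column]] <- values[ord]
    numeric_columns <- c(numeric_columns, sorter_column)
  }
  if (query$maxrows > 0L && nrow(rows) > query$maxrows)
    rows <- rows[seq_len(query$maxrows), , drop = FALSE]
  rownames(rows) <- NULL

  structure(list(columns = names(rows),
                 rows = rows,
                 matched = matched,
                 total_scanned = n,
                 sorter_column = sorter_column,
                 key_column = table$key_column,
                 numeric_columns = numeric_columns,
                 annotation_columns = table$annotation_columns),
            class = "result_table")
}

#' @export
print.result_table <- function(x, ...) {
  cat(sprintf("<result_table: %d of %d rows matched, %d returned>\n",
              x$matched, x$total_scanned, nrow(x$rows)))
  print(utils::head(x$rows, 10L))
  if (nrow(x$rows) > 10L) cat(sprintf("  ... and %d more rows\n", nrow(x$rows) - 10L))
  invisible(x)
}
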