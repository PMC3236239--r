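# Result export (CSV, JSON), plot-series extraction, and the on-disk
# query store.  All formats are plain text; CSV follows RFC 4180
# (minimal quoting, LF line endings on output) and numbers are written
# at full precision so an export/re-load round-trip is lossless.

#' Export a result table as CSV text
#'
#' @param result a `result_table` from [run_query()].
#' @param selection `"all"` (default) or a vector of 1-based row
#'   indices into the result, in the order they should be exported.
#' @return a single CSV string: header line plus one line per selected
#'   row, LF-separated.  Fields containing a comma, quote or newline
#'   are double-quoted.
#' @export
export_csv <- function(result, selection = "all") {
  stopifnot(inherits(result, "result_table"))
  rows <- result$rows
  if (!identical(selection, "all")) {
    selection <- as.integer(selection)
    if (any(is.na(selection)) || any(selection < 1L) ||
        any(selection > nrow(rows)))
      xq_selection_error(sprintf("selection indices must be in 1..%d", nrow(rows)))
    rows <- rows[selection, , drop = FALSE]
  }
  fields <- lapply(names(rows), function(cn) {
    col <- rows[[cn]]
    if (is.numeric(col)) {
      s <- format_full_precision(col)
      s[is.na(s)] <- "NA"
      s
    } else {
      s <- as.character(col)
      s[is.na(s)] <- ""
      csv_escape(s, ",")
    }
  })
  header <- paste(csv_escape(names(rows), ","), collapse = ",")
  if (nrow(rows) == 0L) return(paste0(header, "\n"))
  body <- do.call(paste, c(fields, sep = ","))
  paste0(paste(c(header, body), collapse = "\n"), "\n")
}

#' Serialize a result table to JSON
#'
#' The document has stable key order: `columns`, `rows` (array of
#' per-row arrays, cell order matching `columns`), `matched`,
#' `total_scanned`, plus `sorter_column`, `key_column`,
#' `numeric_columns` and `annotation_columns` so the object round-trips
#' through [deserialize_result()].  Undefined numeric cells are encoded
#' as `null`.
#'
#' @param result a `result_table`.
#' @param pretty pretty-print the JSON.
#' @return JSON text.
#' @export
serialize_result <- function(result, pretty = FALSE) {
  stopifnot(inherits(result, "result_table"))
  rows <- result$rows
  row_list <- lapply(seq_len(nrow(rows)), function(i) {
    lapply(names(rows), function(cn) {
      v <- rows[[cn]][[i]]
      if (is.na(v)) NULL else v
    })
  })
  doc <- list(columns = as.list(result$columns),
              rows = row_list,
              matched = result$matched,
              total_scanned = result$total_scanned,
              sorter_column = result$sorter_column,
              key_column = result$key_column,
              numeric_columns = as.list(result$numeric_columns),
              annotation_columns = as.list(result$annotation_columns))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                                na = "null", digits = I(17), pretty = pretty))
}

#' Rebuild a result table from its JSON serialization
#'
#' @param json JSON text produced by [serialize_result()].
#' @return a `result_table` structurally equal to the serialized one.
#' @export
deserialize_result <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  columns <- vapply(doc$columns, as.character, character(1))
  numeric_columns <- vapply(doc$numeric_columns, as.character, character(1))
  annotation_columns <- vapply(doc$annotation_columns, as.character, character(1))
  n <- length(doc$rows)
  cols <- lapply(seq_along(columns), function(j) {
    cells <- lapply(doc$rows, `[[`, j)
    if (columns[[j]] %in% numeric_columns) {
      vapply(cells, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
             numeric(1))
    } else {
      vapply(cells, function(v) if (is.null(v)) NA_character_ else as.character(v),
             character(1))
    }
  })
  rows <- as.data.frame(stats::setNames(cols, columns),
                        stringsAsFactors = FALSE, check.names = FALSE)
  if (n == 0L) {
    rows <- as.data.frame(stats::setNames(
      lapply(columns, function(cn)
        if (cn %in% numeric_columns) numeric(0) else character(0)),
      columns), stringsAsFactors = FALSE, check.names = FALSE)
  }
  structure(list(columns = columns,
                 rows = rows,
                 matched = as.integer(doc$matched),
                 total_scanned = as.integer(doc$total_scanned),
                 sorter_column = if (is.null(doc$sorter_column)) NULL
                                 else as.character(doc$sorter_column),
                 key_column = as.character(doc$key_column),
                 numeric_columns = numeric_columns,
                 annotation_columns = annotation_columns),
            class = "result_table")
}

#' Extract per-column value series for plotting
#'
#' @param result a `result_table`.
#' @param columns numeric column names (sample columns or the appended
#'   sorter column).
#' @return named list of numeric vectors in result-row order; missing
#'   values are preserved as `NA` gaps.
#' @export
extract_series <- function(result, columns) {
  stopifnot(inherits(result, "result_table"))
  bad <- setdiff(columns, result$numeric_columns)
  if (length(bad))
    xq_selection_error(sprintf("not numeric result columns: %s",
                               paste(bad, collapse = ", ")))
  stats::setNames(lapply(columns, function(cn) as.numeric(result$rows[[cn]])),
                  columns)
}

# --- query store -----------------------------------------------------------

#' Construct a saved query
#'
#' @param name unique label within a store.
#' @param spec a [query_spec()].
#' @param datasets names of the datasets the query runs over.
#' @param created ISO-8601 timestamp; defaults to now (UTC).
#' @return a `saved_query`.
#' @export
saved_query <- function(name, spec, datasets = character(0),
                        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                         tz = "UTC")) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    xq_input_error("query name must be a non-empty string")
  stopifnot(inherits(spec, "query_spec"))
  structure(list(name = name, spec = spec,
                 datasets = as.character(datasets), created = created),
            class = "saved_query")
}

read_store <- function(path) {
  if (!file.exists(path)) return(list())
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

# Atomic at file level: write to a temp file in the same directory,
# then rename over the old store.
write_store <- function(store, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json")
  writeLines(as.character(jsonlite::toJSON(store, auto_unbox = TRUE,
                                           null = "null", pretty = TRUE)),
             tmp)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    xq_input_error(sprintf("cannot write query store %s", path))
  }
  invisible(path)
}

#' Save a query to a store file
#'
#' The store is a single human-readable JSON document keyed by query
#' name.  Saving is atomic: a failed write leaves the previous store
#' intact.
#'
#' @param store path to the store file (created on first save).
#' @param q a [saved_query()].
#' @param overwrite replace an existing entry of the same name;
#'   without it a duplicate name is a conflict error.
#' @return the store path, invisibly.
#' @export
save_query <- function(store, q, overwrite = FALSE) {
  stopifnot(inherits(q, "saved_query"))
  entries <- read_store(store)
  if (q$name %in% names(entries) && !overwrite)
    xq_conflict_error(sprintf("query '%s' already exists (use overwrite)", q$name))
  entries[[q$name]] <- list(filter = q$spec$filter,
                            sorter = q$spec$sorter,
                            maxrows = q$spec$maxrows,
                            descending = q$spec$descending,
                            datasets = as.list(q$datasets),
                            created = q$created)
  write_store(entries, store)
}

#' Load a saved query by name
#'
#' @param store path to the store file.
#' @param name saved query name.
#' @return the [saved_query()]; its `spec` round-trips structurally
#'   (filter and sorter compare equal as re-parsed ASTs).
#' @export
load_query <- function(store, name) {
  entries <- read_store(store)
  if (!name %in% names(entries))
    xq_notfound_error(sprintf("no saved query named '%s'", name))
  e <- entries[[name]]
  saved_query(name,
              query_spec(filter = e$filter, sorter = e$sorter,
                         maxrows = e$maxrows, descending = e$descending),
              datasets = unlist(e$datasets) %||% character(0),
              created = e$created)
}

#' List saved query names in insertion order
#'
#' @param store path to the store file.
#' @return character vector of names (empty when the store does not
#'   exist yet).
#' @export
list_queries <- function(store) {
  names(read_store(store)) %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
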