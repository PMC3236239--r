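# Tokens treated as missing values when reading delimited tables.
MISSING_TOKENS <- c("", "na", "nan", "null")

# Annotation column names recognised (case-insensitively) on load.
ANNOTATION_NAMES <- c("description", "goterms")

is_missing_token <- function(x) tolower(trimws(x)) %in% MISSING_TOKENS

# Shortest decimal representation that survives a write/read round-trip.
format_full_precision <- function(x) {
  s <- as.character(x)
  back <- suppressWarnings(as.numeric(s))
  bad <- !is.na(x) & (is.na(back) | back != x)
  s[bad] <- sprintf("%.17g", x[bad])
  s[is.na(x)] <- NA_character_
  s
}

#' Construct an expression dataset
#'
#' An `expression_dataset` wraps one loaded table: an identifier column,
#' zero or more numeric sample columns (normalised expression values),
#' and optional `description` / `goterms` annotation columns.  Columns
#' that are neither identifier, sample nor annotation are carried along
#' as plain text.
#'
#' @param data data frame holding the table; row order is preserved.
#' @param id_column name of the identifier column.
#' @param name short dataset label used in join provenance.
#' @param sample_columns names of the numeric sample columns; `NULL`
#'   auto-detects every column (other than identifier and annotations)
#'   whose non-missing values are all numeric.
#' @return an object of class `expression_dataset` with fields `name`,
#'   `id_column`, `data`, `sample_columns`, `annotation_columns`.
#' @export
expression_dataset <- function(data, id_column, name = "dataset",
                               sample_columns = NULL) {
  if (!is.data.frame(data)) xq_input_error("`data` must be a data frame")
  if (anyDuplicated(names(data)))
    xq_schema_error(sprintf("duplicate column names: %s",
                            paste(unique(names(data)[duplicated(names(data))]),
                                  collapse = ", ")))
  if (!id_column %in% names(data))
    xq_schema_error(sprintf("identifier column '%s' not found (columns: %s)",
                            id_column, paste(names(data), collapse = ", ")))

  ids <- as.character(data[[id_column]])
  if (nrow(data) > 0 && any(is.na(ids) | !nzchar(trimws(ids))))
    xq_schema_error(sprintf("column '%s' contains empty identifiers", id_column))
  data[[id_column]] <- ids

  annotation <- names(data)[tolower(names(data)) %in% ANNOTATION_NAMES]
  annotation <- setdiff(annotation, id_column)

  if (is.null(sample_columns)) {
    candidates <- setdiff(names(data), c(id_column, annotation))
    sample_columns <- candidates[vapply(candidates, function(cn) {
      col <- data[[cn]]
      if (is.numeric(col)) return(TRUE)
      col <- as.character(col)
      keep <- !is.na(col) & !is_missing_token(col)
      if (!any(keep)) return(FALSE)
      !anyNA(suppressWarnings(as.numeric(col[keep])))
    }, logical(1))]
  } else {
    missing_cols <- setdiff(sample_columns, names(data))
    if (length(missing_cols))
      xq_schema_error(sprintf("sample columns not present: %s",
                              paste(missing_cols, collapse = ", ")))
    if (length(intersect(sample_columns, c(id_column, annotation))))
      xq_schema_error("sample columns may not overlap identifier or annotation columns")
  }

  for (cn in sample_columns) {
    col <- data[[cn]]
    if (!is.numeric(col)) {
      col <- as.character(col)
      col[is_missing_token(col)] <- NA_character_
      col <- suppressWarnings(as.numeric(col))
    }
    col[!is.finite(col)] <- NA_real_   # finite or missing, never Inf/NaN
    data[[cn]] <- col
  }
  for (cn in setdiff(names(data), c(sample_columns))) {
    if (!is.character(data[[cn]])) data[[cn]] <- as.character(data[[cn]])
  }
  for (cn in annotation) data[[cn]][is.na(data[[cn]])] <- ""

  structure(list(name = name,
                 id_column = id_column,
                 data = data,
                 sample_columns = sample_columns,
                 annotation_columns = annotation),
            class = "expression_dataset")
}

#' Load a delimited expression table
#'
#' Reads an RFC-4180-style CSV or a tab-separated text file with a
#' mandatory header row.  Numeric sample columns are auto-detected: a
#' column qualifies when every non-missing cell parses as a number.
#' Missing-value tokens are the empty string, `NA`, `NaN` and `null`
#' (case-insensitive).  Columns named `description` or `goterms`
#' (case-insensitive) are treated as annotation text.
#'
#' @param path file path.
#' @param id_column name of the identifier column (must be in the header).
#' @param name dataset label; defaults to the file name without extension.
#' @param delimiter `"auto"` (by extension: `.csv` is comma, anything
#'   else tab), `","` or `"\t"`.
#' @param prefix optional string prepended (with `_`) to every sample
#'   column name, used to keep column names globally unique across
#'   datasets before a join.
#' @return an [expression_dataset()].
#' @export
load_dataset <- function(path, id_column, name = NULL, delimiter = "auto",
                         prefix = NULL) {
  if (!file.exists(path)) xq_input_error(sprintf("file not found: %s", path))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  sep <- switch(delimiter,
                auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t",
                ","  = ",",
                "\t" = "\t",
                xq_config_error(sprintf("unsupported delimiter %s", deparse(delimiter))))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0 || !nzchar(first))
    xq_input_error(sprintf("empty file: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0), comment.char = "",
                          stringsAsFactors = FALSE, fill = FALSE,
                          encoding = "UTF-8")
  ds <- expression_dataset(df, id_column = id_column, name = name)
  if (!is.null(prefix) && nzchar(prefix)) {
    new <- paste(prefix, ds$sample_columns, sep = "_")
    names(ds$data)[match(ds$sample_columns, names(ds$data))] <- new
    ds$sample_columns <- new
  }
  ds
}

#' Write an expression dataset to a delimited file
#'
#' The inverse of [load_dataset()]: numeric cells are written at full
#' precision so that a load/write/load round-trip preserves all values
#' and row order.  Missing numeric cells are written as `NA`.
#'
#' @param dataset an [expression_dataset()].
#' @param path output path; the delimiter follows the extension
#'   (`.csv` comma, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- dataset$data
  out <- vapply(names(df), function(cn) {
    col <- df[[cn]]
    if (is.numeric(col)) {
      s <- format_full_precision(col)
      s[is.na(s)] <- "NA"
      s
    } else {
      s <- as.character(col)
      s[is.na(s)] <- ""
      csv_escape(s, sep)
    }
  }, character(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(df)))
  if (nrow(df) == 0L) out <- matrix(character(0), nrow = 0L, ncol = ncol(df),
                                    dimnames = list(NULL, names(df)))
  lines <- c(paste(csv_escape(names(df), sep), collapse = sep),
             apply(out, 1L, paste, collapse = sep))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Quote a field when it contains the separator, a quote or a newline.
csv_escape <- function(x, sep = ",") {
  x <- as.character(x)
  needs <- grepl(sprintf('[%s"\n\r]', if (sep == ",") "," else "\t"), x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset '%s': %d rows, key '%s'>\n",
              x$name, nrow(x$data), x$id_column))
  cat("  sample columns:    ", paste(x$sample_columns, collapse = ", "), "\n")
  if (length(x$annotation_columns))
    cat("  annotation columns:", paste(x$annotation_columns, collapse = ", "), "\n")
  invisible(x)
}

#' Join expression datasets on a shared identifier
#'
#' Pre-joins several datasets into the single table queries run
#' against, mirroring how associative queries operate over one wide
#' table keyed by gene or transcript identifier.
#'
#' @param datasets list of [expression_dataset()] objects, all keyed by
#'   `key`.
#' @param key the shared identifier column name.
#' @param policy `"inner"` (default; keys present in every dataset) or
#'   `"left"` (keys of the first dataset, absent cells missing).
#' @return a `joined_table`: fields `key_column`, `data`, `provenance`
#'   (column name to source dataset), `numeric_columns`,
#'   `annotation_columns`.
#' @export
join_datasets <- function(datasets, key, policy = c("inner", "left")) {
  policy <- match.arg(policy)
  if (!length(datasets)) xq_join_error("no datasets to join")
  for (ds in datasets) {
    if (!inherits(ds, "expression_dataset"))
      xq_join_error("all elements must be expression_dataset objects")
    if (!identical(ds$id_column, key))
      xq_join_error(sprintf("dataset '%s' is keyed by '%s', not '%s'",
                            ds$name, ds$id_column, key))
    dup <- ds$data[[key]][duplicated(ds$data[[key]])]
    if (length(dup))
      xq_join_error(sprintf("dataset '%s' has duplicate identifiers (e.g. '%s')",
                            ds$name, dup[[1]]))
  }

  all_samples <- unlist(lapply(datasets, `[[`, "sample_columns"))
  if (anyDuplicated(all_samples))
    xq_join_error(sprintf(
      "sample column name collision across datasets: %s (load with a per-dataset prefix)",
      paste(unique(all_samples[duplicated(all_samples)]), collapse = ", ")))

  keys <- datasets[[1]]$data[[key]]
  if (policy == "inner") {
    for (ds in datasets[-1]) keys <- keys[keys %in% ds$data[[key]]]
  }

  data <- data.frame(keys, stringsAsFactors = FALSE)
  names(data) <- key
  provenance <- stats::setNames(datasets[[1]]$name, key)
  numeric_columns <- character(0)
  annotation_columns <- character(0)

  for (ds in datasets) {
    idx <- match(keys, ds$data[[key]])
    for (cn in setdiff(names(ds$data), key)) {
      out_name <- cn
      if (out_name %in% names(data)) {
        if (cn %in% ds$sample_columns)
          xq_join_error(sprintf("column collision on '%s'", cn))
        out_name <- paste(cn, ds$name, sep = "_")  # later annotation duplicate
        if (out_name %in% names(data))
          xq_join_error(sprintf("column collision on '%s'", out_name))
      }
      col <- ds$data[[cn]][idx]
      if (cn %in% ds$annotation_columns && !is.numeric(col)) col[is.na(col)] <- ""
      data[[out_name]] <- col
      provenance[[out_name]] <- ds$name
      if (cn %in% ds$sample_columns) numeric_columns <- c(numeric_columns, out_name)
      if (cn %in% ds$annotation_columns)
        annotation_columns <- c(annotation_columns, out_name)
    }
  }

  structure(list(key_column = key,
                 data = data,
                 provenance = provenance,
                 numeric_columns = numeric_columns,
                 annotation_columns = annotation_columns),
            class = "joined_table")
}

#' Treat a single data frame as a queryable joined table
#'
#' Convenience for querying one table without an explicit join: column
#' kinds are detected with the same rules as [expression_dataset()].
#'
#' @param x a data frame or a single [expression_dataset()].
#' @param key_column identifier column name.
#' @param name provenance label.
#' @return a `joined_table`.
#' @export
as_joined_table <- function(x, key_column, name = "data") {
  ds <- if (inherits(x, "expression_dataset")) x
        else expression_dataset(x, id_column = key_column, name = name)
  join_datasets(list(ds), key = ds$id_column)
}

#' @export
print.joined_table <- function(x, ...) {
  cat(sprintf("<joined_table: %d rows, key '%s', %d numeric columns>\n",
              nrow(x$data), x$key_column, length(x$numeric_columns)))
  invisible(x)
}
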