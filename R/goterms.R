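# Gene Ontology annotations live inside one text column per table.
# Serialization: entries separated by ";", ID and name separated by "|",
# IDs zero-padded to 7 digits with a "GO:" prefix, e.g.
#   "GO:0003677|DNA binding;GO:0045893|positive regulation of transcription"
# Storing the numeric ID inside the cell is what lets a plain substring
# query such as find("3677", goterms) select by accession.

GO_ID_PATTERN <- "^GO:[0-9]{7}$"

#' Normalize a GO accession
#'
#' Bare digits are zero-padded to seven and prefixed with `GO:`;
#' already-prefixed accessions are padded if needed.
#'
#' @param x character vector of accessions or bare digit strings.
#' @return character vector of `GO:NNNNNNN` accessions; entries that
#'   cannot be normalized are returned unchanged.
#' @export
normalize_go_id <- function(x) {
  x <- trimws(as.character(x))
  bare <- grepl("^[0-9]{1,7}$", x)
  x[bare] <- sprintf("GO:%07d", as.integer(x[bare]))
  pref <- grepl("^GO:[0-9]{1,7}$", x) & !grepl(GO_ID_PATTERN, x)
  x[pref] <- sprintf("GO:%07d", as.integer(sub("^GO:", "", x[pref])))
  x
}

#' Parse a serialized goterms cell
#'
#' @param cell raw cell text; `""` or `NA` yields an empty annotation
#'   set.
#' @return data frame with columns `go_id`, `go_name` (one row per
#'   annotation, cell order preserved).  Entries without a `GO:` prefix
#'   but with name text are kept as name-only annotations (empty
#'   `go_id`) with a warning.
#' @export
parse_goterms <- function(cell) {
  empty <- data.frame(go_id = character(0), go_name = character(0),
                      stringsAsFactors = FALSE)
  if (length(cell) != 1L) xq_input_error("parse_goterms takes a single cell")
  if (is.na(cell) || !nzchar(trimws(cell))) return(empty)
  entries <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
  entries <- entries[nzchar(entries)]
  if (!length(entries)) return(empty)
  parts <- strsplit(entries, "|", fixed = TRUE)
  ids <- character(length(entries)); names_ <- character(length(entries))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    if (length(p) >= 2 && grepl("^GO:", p[[1]])) {
      ids[i] <- normalize_go_id(p[[1]]); names_[i] <- paste(p[-1], collapse = "|")
    } else if (length(p) == 1 && grepl("^GO:[0-9]+$", p[[1]])) {
      ids[i] <- normalize_go_id(p[[1]]); names_[i] <- ""
    } else {
      warning(sprintf("goterms entry without GO accession kept as name-only: '%s'",
                      entries[[i]]), call. = FALSE)
      ids[i] <- ""; names_[i] <- paste(p, collapse = "|")
    }
  }
  data.frame(go_id = ids, go_name = names_, stringsAsFactors = FALSE)
}

#' Serialize GO annotations back into cell text
#'
#' Inverse of [parse_goterms()]: `format_goterms(parse_goterms(x))`
#' is the identity on well-formed cells.
#'
#' @param annotations data frame with columns `go_id`, `go_name`.
#' @return single cell string.
#' @export
format_goterms <- function(annotations) {
  if (!nrow(annotations)) return("")
  entry <- ifelse(nzchar(annotations$go_id) & nzchar(annotations$go_name),
                  paste(annotations$go_id, annotations$go_name, sep = "|"),
                  paste0(annotations$go_id, annotations$go_name))
  paste(entry, collapse = ";")
}

#' Load a GO ID-to-name mapping
#'
#' @param path two-column tab-separated file (`go_id` TAB `name`),
#'   no header.
#' @return named character vector keyed by normalized accession.
#' @export
load_go_mapping <- function(path) {
  if (!file.exists(path)) xq_input_error(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          colClasses = "character", comment.char = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) xq_schema_error("GO mapping must have two tab-separated columns")
  stats::setNames(df[[2]], normalize_go_id(df[[1]]))
}

#' Look up the text name of a GO accession
#'
#' Lookup is total: unknown accessions return the sentinel
#' `"unknown term"` rather than raising an error.  Bare digit input is
#' normalized first, so `goterm_name("3677", m)` and
#' `goterm_name("GO:0003677", m)` agree.
#'
#' @param go_id accession (or bare digits).
#' @param mapping named vector from [load_go_mapping()].
#' @return term name string.
#' @export
goterm_name <- function(go_id, mapping) {
  id <- normalize_go_id(go_id)
  out <- unname(mapping[id])
  out[is.na(out)] <- "unknown term"
  out
}

# URL templates; "{id}" is replaced by the percent-encoded identifier.
DEFAULT_LINK_TEMPLATES <- c(
  ensembl = "https://www.ensembl.org/id/{id}",
  refseq  = "https://www.ncbi.nlm.nih.gov/nuccore/{id}"
)

#' Build an external gene-page URL for a record
#'
#' @param record a named list or one-row data frame.
#' @param id_source `"ensembl"` or `"refseq"` (or any key present in
#'   `templates`).
#' @param key_column which field of `record` holds the identifier.
#' @param templates named character vector of URL templates containing
#'   the placeholder `{id}`.
#' @return URL string with the identifier percent-encoded.
#' @export
record_link <- function(record, id_source, key_column,
                        templates = DEFAULT_LINK_TEMPLATES) {
  if (!id_source %in% names(templates) || is.na(templates[[id_source]]))
    xq_config_error(sprintf("no URL template configured for id source '%s'", id_source))
  id <- as.character(record[[key_column]])
  if (length(id) != 1L || is.na(id) || !nzchar(id))
    xq_input_error("record has no identifier value")
  sub("{id}", utils::URLencode(id, reserved = TRUE), templates[[id_source]],
      fixed = TRUE)
}
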