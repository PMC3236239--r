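# Structured conditions so callers (and the CLI) can map failures to
# distinct exit codes instead of grepping messages.

xq_error <- function(message, class, call = sys.call(-1), ...) {
  stop(errorCondition(message,
                      class = c(class, "xq_error"),
                      call = call, ...))
}

xq_schema_error     <- function(msg, ...) xq_error(msg, "xq_schema_error", ...)
xq_input_error      <- function(msg, ...) xq_error(msg, "xq_input_error", ...)
xq_join_error       <- function(msg, ...) xq_error(msg, "xq_join_error", ...)
xq_lex_error        <- function(msg, position = NA_integer_, ...) {
  xq_error(msg, c("xq_lex_error", "xq_parse_error"), position = position, ...)
}
xq_parse_error      <- function(msg, position = NA_integer_, ...) {
  xq_error(msg, "xq_parse_error", position = position, ...)
}
xq_validation_error <- function(msg, ...) xq_error(msg, "xq_validation_error", ...)
xq_config_error     <- function(msg, ...) xq_error(msg, "xq_config_error", ...)
xq_selection_error  <- function(msg, ...) xq_error(msg, "xq_selection_error", ...)
xq_conflict_error   <- function(msg, ...) xq_error(msg, "xq_conflict_error", ...)
xq_notfound_error   <- function(msg, ...) xq_error(msg, "xq_notfound_error", ...)
xq_spec_error       <- function(msg, ...) xq_error(msg, "xq_spec_error", ...)
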