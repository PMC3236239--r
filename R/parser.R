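# FILTER and SORTER expressions share one grammar, parsed by recursive
# descent into a small typed AST.  Precedence, tightest first:
#   parentheses > unary NOT / unary minus > {*, /} > {+, -}
#   > comparisons {>, <, >=, <=, =, ==, !=} > AND > OR
# Keywords (and/or/not/find) are case-insensitive; identifiers are
# case-sensitive and must match column names exactly.  String literals
# take single or double quotes (no escape sequences).

TOKEN_OPS <- c(">=" = "GE", "<=" = "LE", "==" = "EQ", "!=" = "NEQ",
               ">" = "GT", "<" = "LT", "=" = "EQ",
               "+" = "PLUS", "-" = "MINUS", "*" = "STAR", "/" = "SLASH",
               "(" = "LPAREN", ")" = "RPAREN", "," = "COMMA")

#' Tokenize a query expression
#'
#' Whitespace is insignificant.  `!` followed by optional whitespace and
#' `=` lexes as a single not-equal token (printed query examples
#' sometimes typeset `!=` with an internal space).
#'
#' @param text non-empty expression string.
#' @return data frame with columns `type`, `value`, `pos` (1-based
#'   character offset), terminated by an `EOF` token.
#' @export
tokenize <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    xq_lex_error("empty expression")
  n <- nchar(text)
  i <- 1L
  types <- character(0); values <- character(0); poss <- integer(0)
  emit <- function(type, value, pos) {
    types <<- c(types, type); values <<- c(values, value); poss <<- c(poss, pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[ \t\r\n]$", ch)) { i <- i + 1L; next }
    rest <- substr(text, i, n)
    if (ch %in% c('"', "'")) {
      m <- regexpr(paste0("^", ch, "[^", ch, "]*", ch), rest)
      if (m == -1L)
        xq_lex_error(sprintf("unterminated string literal at position %d", i),
                     position = i)
      len <- attr(m, "match.length")
      emit("STRING", substr(rest, 2L, len - 1L), i)
      i <- i + len; next
    }
    if (grepl("^[0-9.]", ch) && grepl("^[0-9]|^\\.[0-9]", rest)) {
      m <- regexpr("^([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?", rest)
      len <- attr(m, "match.length")
      emit("NUMBER", substr(rest, 1L, len), i)
      i <- i + len; next
    }
    if (grepl("^[A-Za-z_]", ch)) {
      m <- regexpr("^[A-Za-z_][A-Za-z0-9_.]*", rest)
      len <- attr(m, "match.length")
      word <- substr(rest, 1L, len)
      lw <- tolower(word)
      type <- switch(lw, and = "AND", or = "OR", not = "NOT", find = "FIND",
                     "IDENT")
      emit(type, word, i)
      i <- i + len; next
    }
    if (ch == "!") {
      m <- regexpr("^![ \t]*=", rest)
      if (m == -1L)
        xq_lex_error(sprintf("expected '=' after '!' at position %d", i),
                     position = i)
      emit("NEQ", "!=", i)
      i <- i + attr(m, "match.length"); next
    }
    two <- substr(text, i, min(i + 1L, n))
    if (two %in% names(TOKEN_OPS)) {
      emit(TOKEN_OPS[[two]], two, i); i <- i + 2L; next
    }
    if (ch %in% names(TOKEN_OPS)) {
      emit(TOKEN_OPS[[ch]], ch, i); i <- i + 1L; next
    }
    xq_lex_error(sprintf("illegal character '%s' at position %d", ch, i),
                 position = i)
  }
  emit("EOF", "", n + 1L)
  data.frame(type = types, value = values, pos = poss,
             stringsAsFactors = FALSE)
}

# --- AST node constructors -------------------------------------------------
# Every node carries `type` and is classed "xq_node"; node_kind() says
# whether it evaluates to a boolean or a number.

xq_node <- function(type, ...) structure(list(type = type, ...), class = "xq_node")

node_num  <- function(value)        xq_node("num", value = value)
node_col  <- function(name)         xq_node("col", name = name)
node_find <- function(needle, col)  xq_node("find", needle = needle, column = col)
node_not  <- function(child)        xq_node("not", child = child)
node_neg  <- function(child)        xq_node("neg", child = child)
node_arith <- function(op, lhs, rhs) xq_node("arith", op = op, lhs = lhs, rhs = rhs)
node_cmp   <- function(op, lhs, rhs) xq_node("cmp", op = op, lhs = lhs, rhs = rhs)
node_and   <- function(lhs, rhs)     xq_node("and", lhs = lhs, rhs = rhs)
node_or    <- function(lhs, rhs)     xq_node("or", lhs = lhs, rhs = rhs)

#' Kind of value an AST node evaluates to
#' @param node an expression node.
#' @return `"bool"` or `"num"`.
#' @export
node_kind <- function(node) {
  if (node$type %in% c("and", "or", "not", "cmp", "find")) "bool" else "num"
}

# --- recursive descent -----------------------------------------------------

new_parser <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$i <- 1L
  env
}
peek <- function(p) p$tokens[p$i, ]
advance <- function(p) { tok <- p$tokens[p$i, ]; p$i <- p$i + 1L; tok }
expect <- function(p, type, what) {
  tok <- peek(p)
  if (tok$type != type)
    xq_parse_error(sprintf("expected %s but found '%s' at position %d",
                           what, if (tok$type == "EOF") "end of expression" else tok$value,
                           tok$pos),
                   position = tok$pos)
  advance(p)
}
require_kind <- function(node, kind, tok, context) {
  if (node_kind(node) != kind)
    xq_parse_error(sprintf("%s at position %d requires a %s operand",
                           context, tok$pos,
                           if (kind == "bool") "boolean" else "numeric"),
                   position = tok$pos)
  node
}

p_or <- function(p) {
  lhs <- p_and(p)
  while (peek(p)$type == "OR") {
    tok <- advance(p)
    require_kind(lhs, "bool", tok, "OR")
    rhs <- require_kind(p_and(p), "bool", tok, "OR")
    lhs <- node_or(lhs, rhs)
  }
  lhs
}
p_and <- function(p) {
  lhs <- p_cmp(p)
  while (peek(p)$type == "AND") {
    tok <- advance(p)
    require_kind(lhs, "bool", tok, "AND")
    rhs <- require_kind(p_cmp(p), "bool", tok, "AND")
    lhs <- node_and(lhs, rhs)
  }
  lhs
}
p_cmp <- function(p) {
  lhs <- p_add(p)
  if (peek(p)$type %in% c("GT", "LT", "GE", "LE", "EQ", "NEQ")) {
    tok <- advance(p)
    op <- c(GT = ">", LT = "<", GE = ">=", LE = "<=", EQ = "=", NEQ = "!=")[[tok$type]]
    if (node_kind(lhs) == "bool")
      xq_parse_error(sprintf("cannot compare boolean expressions at position %d",
                             tok$pos), position = tok$pos)
    rhs <- p_add(p)
    if (node_kind(rhs) == "bool")
      xq_parse_error(sprintf("cannot compare boolean expressions at position %d",
                             tok$pos), position = tok$pos)
    lhs <- node_cmp(op, lhs, rhs)
  }
  lhs
}
p_add <- function(p) {
  lhs <- p_mul(p)
  while (peek(p)$type %in% c("PLUS", "MINUS")) {
    tok <- advance(p)
    require_kind(lhs, "num", tok, "arithmetic")
    rhs <- require_kind(p_mul(p), "num", tok, "arithmetic")
    lhs <- node_arith(if (tok$type == "PLUS") "+" else "-", lhs, rhs)
  }
  lhs
}
p_mul <- function(p) {
  lhs <- p_unary(p)
  while (peek(p)$type %in% c("STAR", "SLASH")) {
    tok <- advance(p)
    require_kind(lhs, "num", tok, "arithmetic")
    rhs <- require_kind(p_unary(p), "num", tok, "arithmetic")
    lhs <- node_arith(if (tok$type == "STAR") "*" else "/", lhs, rhs)
  }
  lhs
}
p_unary <- function(p) {
  tok <- peek(p)
  if (tok$type == "NOT") {
    advance(p)
    child <- require_kind(p_unary(p), "bool", tok, "NOT")
    return(node_not(child))
  }
  if (tok$type == "MINUS") {
    advance(p)
    child <- require_kind(p_unary(p), "num", tok, "unary minus")
    return(node_neg(child))
  }
  p_primary(p)
}
p_primary <- function(p) {
  tok <- peek(p)
  if (tok$type == "NUMBER") {
    advance(p)
    return(node_num(as.numeric(tok$value)))
  }
  if (tok$type == "IDENT") {
    advance(p)
    return(node_col(tok$value))
  }
  if (tok$type == "FIND") {
    advance(p)
    expect(p, "LPAREN", "'(' after find")
    needle <- expect(p, "STRING", "a quoted search string")
    expect(p, "COMMA", "','")
    col <- expect(p, "IDENT", "an annotation column name")
    expect(p, "RPAREN", "')'")
    return(node_find(needle$value, col$value))
  }
  if (tok$type == "LPAREN") {
    advance(p)
    inner <- p_or(p)
    expect(p, "RPAREN", "')'")
    return(inner)
  }
  xq_parse_error(sprintf("unexpected %s at position %d",
                         if (tok$type == "EOF") "end of expression"
                         else sprintf("'%s'", tok$value),
                         tok$pos),
                 position = tok$pos)
}

parse_expression <- function(text) {
  p <- new_parser(tokenize(text))
  node <- p_or(p)
  tok <- peek(p)
  if (tok$type != "EOF")
    xq_parse_error(sprintf("unexpected '%s' at position %d", tok$value, tok$pos),
                   position = tok$pos)
  node
}

#' Parse a FILTER expression
#'
#' @param text boolean expression string.
#' @return an expression node of boolean kind.
#' @export
parse_filter <- function(text) {
  node <- parse_expression(text)
  if (node_kind(node) != "bool")
    xq_parse_error("a filter must be a boolean expression (use a comparison or find())")
  node
}

#' Parse a SORTER expression
#'
#' Sorters are purely arithmetic: they compute the numeric ranking
#' value appended as the last result column.  Boolean constructs
#' (comparisons, AND/OR/NOT, find) are rejected.
#'
#' @param text arithmetic expression string.
#' @return an expression node of numeric kind.
#' @export
parse_sorter <- function(text) {
  node <- parse_expression(text)
  if (node_kind(node) != "bool") return(node)
  xq_parse_error("a sorter must be a numeric expression; boolean operators and find() are not allowed in sorters")
}

#' Validate column references against a joined table
#'
#' @param node an expression node.
#' @param table a `joined_table`.
#' @return character vector of findings: unknown column names, plus
#'   kind mismatches reported as `"name (not a numeric column)"` or
#'   `"name (not an annotation column)"`.  Empty when the node is fully
#'   evaluable against the table.
#' @export
validate_columns <- function(node, table) {
  stopifnot(inherits(node, "xq_node"), inherits(table, "joined_table"))
  findings <- character(0)
  walk <- function(nd) {
    switch(nd$type,
      col = {
        if (!nd$name %in% names(table$data))
          findings <<- c(findings, nd$name)
        else if (!nd$name %in% table$numeric_columns)
          findings <<- c(findings, sprintf("%s (not a numeric column)", nd$name))
      },
      find = {
        if (!nd$column %in% names(table$data))
          findings <<- c(findings, nd$column)
        else if (!nd$column %in% table$annotation_columns)
          findings <<- c(findings, sprintf("%s (not an annotation column)", nd$column))
      },
      num = NULL,
      not = walk(nd$child),
      neg = walk(nd$child),
      { walk(nd$lhs); walk(nd$rhs) })
  }
  walk(node)
  unique(findings)
}

#' Render an expression node back to query text
#'
#' Output is fully parenthesized; `parse_filter(render_expression(x))`
#' (or `parse_sorter` for numeric nodes) reproduces `x` structurally,
#' and rendering is idempotent on already-rendered strings.
#'
#' @param node an expression node.
#' @return canonical expression string.
#' @export
render_expression <- function(node) {
  stopifnot(inherits(node, "xq_node"))
  switch(node$type,
    num = format_full_precision(node$value),
    col = node$name,
    find = {
      q <- if (!grepl('"', node$needle, fixed = TRUE)) '"'
           else if (!grepl("'", node$needle, fixed = TRUE)) "'"
           else xq_input_error("find() needle contains both quote characters; the grammar has no escapes")
      sprintf("find(%s%s%s,%s)", q, node$needle, q, node$column)
    },
    not = sprintf("(NOT %s)", render_expression(node$child)),
    neg = sprintf("(-%s)", render_expression(node$child)),
    and = sprintf("(%s AND %s)", render_expression(node$lhs), render_expression(node$rhs)),
    or  = sprintf("(%s OR %s)",  render_expression(node$lhs), render_expression(node$rhs)),
    sprintf("(%s %s %s)", render_expression(node$lhs), node$op,
            render_expression(node$rhs)))
}

#' @export
print.xq_node <- function(x, ...) {
  cat("<query expression> ", render_expression(x), "\n", sep = "")
  invisible(x)
}
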