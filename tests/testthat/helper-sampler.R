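# Random well-formed query generation for property-style tests.
# Numeric expressions draw from the fixture's sample columns; boolean
# expressions bottom out in comparisons or find() predicates.

SAMPLER_NUMERIC_COLS <- c("sg3", "mes1", "dmrt1binding", "eye")
SAMPLER_ANNOT_COLS <- c("description", "goterms")
SAMPLER_NEEDLES <- c("hox", "protein", "dna binding", "3677", "binding",
                     "transcription factor", "activator", "kinase",
                     "zzz-no-match")

sample_numeric_ast <- function(depth,
                               columns = SAMPLER_NUMERIC_COLS) {
  leaf <- depth <= 0 || stats::runif(1) < 0.3
  if (leaf) {
    if (stats::runif(1) < 0.6)
      exprquery:::node_col(sample(columns, 1))
    else
      exprquery:::node_num(sample(c(0, 1, 2, 5, 10, 200, 0.5), 1))
  } else {
    op <- sample(c("+", "-", "*", "/", "neg"), 1,
                 prob = c(0.3, 0.2, 0.2, 0.25, 0.05))
    if (op == "neg") exprquery:::node_neg(sample_numeric_ast(depth - 1, columns))
    else exprquery:::node_arith(op,
                                sample_numeric_ast(depth - 1, columns),
                                sample_numeric_ast(depth - 1, columns))
  }
}

sample_bool_ast <- function(depth,
                            columns = SAMPLER_NUMERIC_COLS,
                            annot = SAMPLER_ANNOT_COLS,
                            needles = SAMPLER_NEEDLES) {
  leaf <- depth <= 0 || stats::runif(1) < 0.35
  if (leaf) {
    if (stats::runif(1) < 0.7) {
      op <- sample(c(">", "<", ">=", "<=", "=", "!="), 1)
      exprquery:::node_cmp(op,
                           sample_numeric_ast(depth - 1, columns),
                           sample_numeric_ast(depth - 1, columns))
    } else {
      exprquery:::node_find(sample(needles, 1), sample(annot, 1))
    }
  } else {
    kind <- sample(c("and", "or", "not"), 1, prob = c(0.4, 0.4, 0.2))
    if (kind == "not") exprquery:::node_not(sample_bool_ast(depth - 1, columns,
                                                            annot, needles))
    else if (kind == "and") exprquery:::node_and(
      sample_bool_ast(depth - 1, columns, annot, needles),
      sample_bool_ast(depth - 1, columns, annot, needles))
    else exprquery:::node_or(
      sample_bool_ast(depth - 1, columns, annot, needles),
      sample_bool_ast(depth - 1, columns, annot, needles))
  }
}

sample_query_texts <- function(depth = 5) {
  list(filter = render_expression(sample_bool_ast(depth)),
       sorter = if (stats::runif(1) < 0.85)
                  render_expression(sample_numeric_ast(min(depth, 3)))
                else "",
       maxrows = sample(c(0L, 1L, 5L, 50L, 2000L), 1),
       descending = sample(c(TRUE, FALSE), 1))
}
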