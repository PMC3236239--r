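---
title: "Query semantics, design choices and synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Query semantics, design choices and synthetic benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprquery)
```

## The querying model

`exprquery` evaluates a three-part query — FILTER, SORTER, MAXROWS —
over a single wide table produced by pre-joining all participating
datasets on a shared gene/transcript/probe identifier. The three parts
are deliberately independent: the same filter can be re-ranked by
different sorters, and the sorter value is always materialised as the
last result column (`sorter_value`) so the ranking criterion is visible
in the output, exportable, and plottable like any sample column.

The pipeline order is fixed and mirrors SQL `WHERE` → `ORDER BY` →
`LIMIT`: rows are filtered first, the sorter is computed only for
matching rows, sorting happens on that value, and MAXROWS truncates
the *sorted* result. Truncating before sorting would silently change
which rows a "top 50" query returns, so it is not offered.

### Grammar and precedence

One expression grammar serves filters and sorters, parsed by recursive
descent into a typed AST. Precedence, tightest first: parentheses,
unary `NOT`/`-`, `* /`, `+ -`, comparisons
(`> < >= <= = == != `), `AND`, `OR`. Keywords are case-insensitive
(`and`/`AND` are the same token); identifiers are case-sensitive and
must match column names exactly, which avoids ambiguity with
mixed-case sample names such as `ICAP1`. String literals accept single
or double quotes and contain no escape sequences. `!=` may be typeset
with internal whitespace (`! =`) and still lexes as one token, since
printed query examples sometimes appear that way.

Type checking happens during parsing: comparisons require numeric
operands, `AND`/`OR`/`NOT` require boolean operands, a filter must be
boolean overall and a sorter must be numeric overall (so
`parse_sorter("sg3>mes1")` is a parse error, not a silent coercion).
`render_expression()` emits a fully parenthesised canonical form;
`parse ∘ render` is the identity on ASTs and `render ∘ parse` is
idempotent on strings, which is what makes saved queries and
round-trip tests trustworthy.

### Three-valued logic

Expression tables routinely contain missing cells, and fold-change
filters routinely divide by zero. Both are handled with SQL-style
three-valued logic rather than errors: an arithmetic expression with a
missing operand, or any non-finite intermediate (division by zero),
is *undefined*; a comparison on an undefined operand is undefined; and
`AND`/`OR`/`NOT` follow the Kleene tables (`undefined OR TRUE` is
`TRUE`, `undefined AND FALSE` is `FALSE`). A row is selected only when
its filter is definitely `TRUE` — so `result(F)` and `result(NOT F)`
partition exactly the rows where `F` is defined, and rows with missing
data never leak into either side.

`find(needle, column)` is the exception: it is two-valued. Substring
search over an absent or empty annotation is a definite non-match, not
an unknown, because the question "does the text mention X" has a
definite answer ("no") when there is no text. Matching is
case-insensitive — published usage searches for lower-case
`"dna binding"` against conventionally capitalised GO names — and
works on the raw serialized cell text, so numeric GO accessions are
searchable as plain substrings (`find("3677",goterms)`).

### Sorting

The default direction is descending (fold-change queries ask for the
*most* regulated candidates first); `descending = FALSE` is the
"inverted" sorter used to surface the least expressed candidates.
Direction is a query parameter, not expression syntax. Ties keep input
order (stable radix sort), undefined sorter values always sort after
all defined values, and numeric comparison is exact floating-point —
no epsilon — trading forgiveness for bit-level reproducibility:
identical inputs yield byte-identical serialized results.

## Data model choices

* **Join policy.** The default is an inner join (the key set is the
  intersection), because queries typically reference columns from every
  joined dataset and a row missing one side is undefined under almost
  any such filter anyway. A left join is available for exploratory
  use. One key per join: a table is joined on exactly one identifier
  column at a time.
* **Duplicate identifiers** within one dataset are an error, not
  silently aggregated — the one-row-per-gene model is what makes
  pre-joined querying interpretable. Aggregation policy is the user's
  job upstream.
* **Column collisions.** Sample columns must be globally unique;
  the loader's per-dataset `prefix` makes this explicit rather than
  silent. Annotation columns (`description`, `goterms`) are taken from
  the first dataset providing them; later duplicates are kept with a
  dataset-name suffix.
* **GO serialization.** Annotations are stored as
  `GO:0003677|DNA binding;GO:0045893|...` — `;` between entries, `|`
  between the zero-padded 7-digit accession and the name. Keeping the
  digits inside the cell is what makes accession substring queries
  work with the same `find()` primitive as free text.
* **Missing-value tokens** on load: empty string, `NA`, `NaN`, `null`
  (case-insensitive). Loaded sample values are forced finite-or-missing
  (a parsed `Inf` becomes missing).
* **Full-precision numerics.** CSV export and the JSON result document
  write numbers with the shortest representation that round-trips the
  double (up to 17 significant digits), so export → re-load is
  lossless, a property the test suite checks structurally.

## What the synthetic fixtures emulate

The two generators reproduce the *shape* of the two study designs this
kind of tool is used on, not their biology:

* `generate_medaka_like()` — a deep-sequencing comparison of two fish
  stem-cell lines: log-normal (long-tailed, non-negative) expression
  columns `sg3`, `mes1`, `eye` keyed by Ensembl-style transcript IDs,
  GO and description annotations, plus a companion per-transcript
  `dmrt1binding` score table to exercise cross-dataset joins.
  Defaults: 500 rows, seed 7.
* `generate_huvec_like()` — a three-condition endothelial microarray
  (`gfp` control, `notch1`, `ICAP1`) keyed by probe ID, with uniform
  array-like intensities. Defaults: 400 rows, seed 3.

The signal rows are **constructed, not sampled**: exactly 25 rows (by
default) carry both a "transcription factor" and an "activator" GO
name, exactly 10 of those get a binding score above 10, exactly 120
microarray rows satisfy `gfp>notch1 AND gfp>ICAP1`, and one designated
row is built to have the strictly largest `gfp/((notch1+ICAP1)/2)`
ratio. The GO vocabulary is partitioned so no unplanted row can match
the conjunction by accident. This makes planted counts exact query
answers — the generator's bookkeeping is the test oracle. Distribution
choices (log-normal vs. uniform) are cosmetic realism; only the
planted combinatorial structure carries information, and passing these
tests therefore demonstrates correct query semantics, not robustness
to real-data pathologies (batch effects, unnormalised libraries,
malformed annotations from live databases).

## Verification strategy and problem sizes

Beyond unit tests, the suite checks run-for-run equivalence between
the vectorized engine and a deliberately naive reference interpreter —
scalar recursion per row with explicit Kleene truth tables, an
explicit tie-break index for the reference sort, truncation after
sorting — over randomly generated ASTs (depth ≤ 5–6) on seeded random
tables with ~6% missing cells and planted sort ties. The acceptance
script runs 200 sampled queries on a 1,000-row table; in-suite
property tests use 150–400 rows and 15–40 queries per property, sizes
chosen to exercise every operator and edge without inflating runtimes.
Logic invariants (conjunction shrinks result sets, disjunction grows
them, `F`/`NOT F` partition defined rows, MAXROWS is a prefix of the
untruncated order) are tested the same way.

## Known limitations

* The language has no aggregates, no subqueries, no string comparison
  operators, and no modulo — only the constructs above.
* Tables are scanned linearly per query; there is no indexing. This is
  a desk-scale tool (tens of thousands of rows), not a database.
* `find()` has no regular expressions; needles are literal substrings.
* One identifier column per join; joining the same pair of tables on
  two different keys simultaneously is not expressible.
* The GO mapping used for name lookup is user-supplied; the package
  bundles only the ~30-term vocabulary its generators use.
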