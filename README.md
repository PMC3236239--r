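# exprquery

`exprquery` is an R package for asking simple, free-form questions of
normalized transcriptome tables — bulk RNA-seq read counts, microarray
intensities, or any per-gene numeric scores — without a database server
or bioinformatics pipeline. It is aimed at bench scientists who receive
a processed expression table and want to filter, rank and
cross-associate it interactively or from a shell.

A query has three independent parts, in the spirit of a SQL
`SELECT ... WHERE ... ORDER BY ... LIMIT`:

* **FILTER** — a boolean expression over the table's columns that
  selects rows, e.g. a fold-change rule `sg3/mes1>10 and mes1>5`, or a
  text predicate over annotations, `find("dna binding",goterms)`.
* **SORTER** — an arithmetic expression computed per matching row,
  appended as the last result column (`sorter_value`) and used for
  ordering, e.g. `gfp/((notch1+ICAP1)/2)` to rank by mean fold change
  against two treatments.
* **MAXROWS** — a row limit applied *after* sorting.

Expressions support `+ - * /`, comparisons (`> < >= <= = !=`),
`AND / OR / NOT` (case-insensitive), parentheses, and
`find(needle, column)` — case-insensitive substring search over the
`description` or `goterms` annotation columns. Evaluation uses
three-valued logic: a missing cell or a division by zero makes a
subexpression undefined (like SQL `NULL`), and a row is only returned
when its filter is definitely true. `find()` on an empty annotation is
a definite non-match.

Before querying, any number of tables sharing an identifier column
(gene ID, transcript ID, probe ID) are **pre-joined** into one wide
table, so a per-transcript binding score table can be combined with an
expression table and filtered jointly
(`... AND dmrt1binding>10`).

## Worked example

Generate a synthetic stem-cell–style fixture (500 transcripts with
`sg3`/`mes1`/`eye` expression, GO annotations, and a joinable
`dmrt1binding` score table), join, and ask for lowly expressed
transcription-activator candidates:

```r
library(exprquery)

fx  <- generate_medaka_like()          # deterministic, seed 7
tbl <- join_datasets(list(fx$expression, fx$binding), key = "transcript_id")

q <- query_spec(
  filter  = "find('transcription factor',goterms) and find('activator',goterms)",
  sorter  = "(sg3+mes1)",
  maxrows = 5,
  descending = FALSE)                  # "inverted" sorter: smallest first

res <- run_query(tbl, q)
res
#> <result_table: 25 of 500 rows matched, 5 returned>
#>        transcript_id       sg3      mes1       eye  ...  dmrt1binding sorter_value
#> 1 ENSORLT00000000006 1.7843962 0.3713536  9.014486  ...     7.1951972     2.155750
#> 2 ENSORLT00000000089 0.5072049 3.1193980 12.404095  ...     0.4514801     3.626603
#> 3 ENSORLT00000000274 1.4464322 3.8143486 10.006977  ...    12.0991875     5.260781
#> 4 ENSORLT00000000249 0.4755473 6.0403937  5.004804  ...     9.1697129     6.515941
#> 5 ENSORLT00000000409 6.3745493 1.0897856  1.004299  ...    35.6703605     7.464335
```

`matched` (25) is the number of rows passing the filter out of
`total_scanned` (500); the appended `sorter_value` column holds the
per-row `(sg3+mes1)` expression sum, here ascending so the least
expressed candidates come first. Results export with `export_csv()` /
`serialize_result()`, plot series come from `extract_series()`, and
queries persist by name via `save_query()` / `load_query()`.

The same works from a shell through the bundled CLI
(`system.file("cli", "exprquery", package = "exprquery")`), with
subcommands `query`, `save`, `load`, `list`, `fixtures`, `goterm` and
`link`; results go to stdout, logs to stderr, and error classes map to
distinct exit codes.

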