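test_that("eval_numeric does standard arithmetic and propagates undefined", {
  expect_equal(eval_numeric(list(sg3 = 50, mes1 = 4), "sg3/mes1"), 12.5)
  expect_true(is.na(eval_numeric(list(sg3 = 50, mes1 = 0), "sg3/mes1")))
  expect_equal(eval_numeric(list(gfp = 30, notch1 = 10, ICAP1 = 20),
                            "gfp/((notch1+ICAP1)/2)"), 2.0)
  expect_true(is.na(eval_numeric(list(sg3 = NA, mes1 = 4), "sg3+mes1")))
  expect_equal(eval_numeric(list(sg3 = 3), "-sg3"), -3)
})

test_that("comparisons with an undefined operand are undefined", {
  expect_true(eval_boolean(list(sg3 = 50, mes1 = 4, dmrt1binding = 1),
                           "sg3>mes1 and mes1>dmrt1binding"))
  expect_true(is.na(eval_boolean(list(sg3 = 50, mes1 = NA), "sg3>mes1")))
  # OR absorbs undefined when the other side is definitely true
  expect_true(eval_boolean(list(sg3 = 300, mes1 = NA), "sg3>mes1 OR sg3>200"))
})

test_that("AND/OR/NOT follow the Kleene three-valued truth tables", {
  # encode T / F / undefined through comparisons on (x, y) pairs
  states <- list(T = c(1, 0), F = c(0, 1), U = c(1, NA))
  and_expected <- matrix(c("T", "F", "U",
                           "F", "F", "F",
                           "U", "F", "U"),
                         nrow = 3, byrow = TRUE,
                         dimnames = list(c("T", "F", "U"), c("T", "F", "U")))
  or_expected <- matrix(c("T", "T", "T",
                          "T", "F", "U",
                          "T", "U", "U"),
                        nrow = 3, byrow = TRUE,
                        dimnames = list(c("T", "F", "U"), c("T", "F", "U")))
  decode <- function(v) if (is.na(v)) "U" else if (v) "T" else "F"
  for (a in names(states)) for (b in names(states)) {
    row <- list(x1 = states[[a]][1], y1 = states[[a]][2],
                x2 = states[[b]][1], y2 = states[[b]][2])
    expect_identical(decode(eval_boolean(row, "x1>y1 AND x2>y2")),
                     and_expected[a, b], info = paste(a, "AND", b))
    expect_identical(decode(eval_boolean(row, "x1>y1 OR x2>y2")),
                     or_expected[a, b], info = paste(a, "OR", b))
  }
  not_expected <- c(T = "F", F = "T", U = "U")
  for (a in names(states)) {
    row <- list(x1 = states[[a]][1], y1 = states[[a]][2])
    expect_identical(decode(eval_boolean(row, "NOT (x1>y1)")),
                     not_expected[[a]], info = paste("NOT", a))
  }
})

test_that("find() is case-insensitive substring match and never undefined", {
  row <- list(description = "homeobox protein HoxB4",
              goterms = "GO:0003677|DNA binding")
  expect_true(eval_boolean(row, 'find("hox",description)'))
  expect_true(eval_boolean(row, 'find("3677",goterms)'))
  expect_true(eval_boolean(row, 'find("dna binding",goterms)'))
  expect_false(eval_boolean(row, 'find("kinase",goterms)'))
  expect_false(eval_boolean(list(description = ""), 'find("hox",description)'))
  expect_false(eval_boolean(list(description = NA_character_),
                            'find("hox",description)'))
  call <- parse_filter('find("HOX",description)')
  expect_true(eval_find(row, call))
})

test_that("run_query filters, appends the sorter column last, sorts and truncates", {
  tbl <- make_tiny_table()
  res <- run_query(tbl, query_spec(filter = "sg3>mes1", sorter = "sg3+eye",
                                   maxrows = 2L))
  # matching rows: t1 (50>4), t3 is undefined (mes1 NA), t4/t5 not greater
  ref <- oracle_run_query(tbl, "sg3>mes1", "sg3+eye", 2L, TRUE)
  expect_identical(res$rows$transcript_id, ref$rows$transcript_id)
  expect_identical(res$matched, ref$matched)
  expect_identical(res$columns[length(res$columns)], "sorter_value")
  expect_equal(res$rows$sorter_value, ref$rows$sorter_value)
  expect_identical(res$total_scanned, 5L)
})

test_that("empty filter matches all rows; empty sorter keeps input order without a column", {
  tbl <- make_tiny_table()
  res <- run_query(tbl, query_spec())
  expect_identical(res$matched, 5L)
  expect_identical(res$rows$transcript_id, tbl$data$transcript_id)
  expect_null(res$sorter_column)
  expect_false("sorter_value" %in% res$columns)
})

test_that("a filter matching nothing returns an empty result with intact header", {
  tbl <- make_tiny_table()
  res <- run_query(tbl, query_spec(filter = "sg3>99999", sorter = "sg3"))
  expect_identical(nrow(res$rows), 0L)
  expect_identical(res$matched, 0L)
  expect_identical(res$columns, c(names(tbl$data), "sorter_value"))
})

test_that("undefined sorter values sort after all defined values", {
  tbl <- make_tiny_table()   # t3 has mes1 = NA
  res <- run_query(tbl, query_spec(sorter = "sg3/mes1"))
  vals <- res$rows$sorter_value
  expect_true(all(which(is.na(vals)) > max(which(!is.na(vals)))))
  expect_identical(res$rows$transcript_id[nrow(res$rows)], "t3")
  defined <- vals[!is.na(vals)]
  expect_true(all(diff(defined) <= 0))  # descending by default
  asc <- run_query(tbl, query_spec(sorter = "sg3/mes1", descending = FALSE))
  expect_true(all(diff(asc$rows$sorter_value[!is.na(asc$rows$sorter_value)]) >= 0))
})

test_that("ties are broken by input order (stable sort)", {
  df <- data.frame(id = c("a", "b", "c", "d"),
                   x = c(5, 9, 5, 9), stringsAsFactors = FALSE)
  tbl <- as_joined_table(df, "id")
  res <- run_query(tbl, query_spec(sorter = "x"))
  expect_identical(res$rows$id, c("b", "d", "a", "c"))
  asc <- run_query(tbl, query_spec(sorter = "x", descending = FALSE))
  expect_identical(asc$rows$id, c("a", "c", "b", "d"))
})

test_that("validation errors surface before any row is scanned", {
  tbl <- make_tiny_table()
  expect_error(run_query(tbl, query_spec(filter = "typo>1")),
               class = "xq_validation_error")
  expect_error(run_query(tbl, query_spec(sorter = "description+1")),
               class = "xq_validation_error")
  expect_error(query_spec(filter = "sg3>"), class = "xq_parse_error")
  expect_error(query_spec(maxrows = -1), class = "xq_input_error")
})

test_that("run_query matches the naive per-row oracle on random queries", {
  tbl <- make_random_table(n = 300, seed = 7)
  withr::with_seed(101, {
    for (i in 1:40) {
      q <- sample_query_texts(depth = 4)
      res <- run_query(tbl, query_spec(q$filter, q$sorter, q$maxrows,
                                       q$descending))
      ref <- oracle_run_query(tbl, q$filter, q$sorter, q$maxrows, q$descending)
      expect_identical(res$matched, ref$matched, info = q$filter)
      expect_equal(res$rows, ref$rows, info = paste(q$filter, "|", q$sorter))
    }
  })
})

test_that("conjunction shrinks and disjunction grows the result set", {
  tbl <- make_random_table(n = 250, seed = 13)
  withr::with_seed(77, {
    for (i in 1:15) {
      f <- render_expression(sample_bool_ast(3))
      g <- render_expression(sample_bool_ast(3))
      ids_f <- run_query(tbl, query_spec(f))$rows$transcript_id
      ids_and <- run_query(tbl, query_spec(sprintf("(%s) AND (%s)", f, g)))$rows$transcript_id
      ids_or <- run_query(tbl, query_spec(sprintf("(%s) OR (%s)", f, g)))$rows$transcript_id
      expect_true(all(ids_and %in% ids_f), info = paste(f, g))
      expect_true(all(ids_f %in% ids_or), info = paste(f, g))
    }
  })
})

test_that("F and NOT F partition the rows where F is defined", {
  tbl <- make_random_table(n = 250, seed = 29)
  withr::with_seed(31, {
    for (i in 1:15) {
      node <- sample_bool_ast(3)
      f <- render_expression(node)
      vals <- vapply(seq_len(nrow(tbl$data)),
                     function(j) oracle_eval(node, as.list(tbl$data[j, ])),
                     logical(1))
      defined <- tbl$data$transcript_id[!is.na(vals)]
      pos <- run_query(tbl, query_spec(f))$rows$transcript_id
      neg <- run_query(tbl, query_spec(sprintf("NOT (%s)", f)))$rows$transcript_id
      expect_length(intersect(pos, neg), 0)
      expect_setequal(union(pos, neg), defined)
    }
  })
})

test_that("maxrows truncates to a prefix of the untruncated sorted result", {
  tbl <- make_random_table(n = 150, seed = 5)
  full <- run_query(tbl, query_spec(filter = "sg3>1", sorter = "sg3*mes1"))
  for (m in c(1L, 7L, 50L, 1000L)) {
    cut <- run_query(tbl, query_spec(filter = "sg3>1", sorter = "sg3*mes1",
                                     maxrows = m))
    expect_lte(nrow(cut$rows), m)
    expect_identical(cut$matched, full$matched)
    expect_identical(cut$rows$transcript_id,
                     utils::head(full$rows$transcript_id, m))
  }
})

test_that("identical inputs give byte-identical serialized results", {
  tbl <- make_random_table(n = 100, seed = 3)
  q <- query_spec(filter = "sg3>mes1 or eye<2", sorter = "sg3-eye", maxrows = 20L)
  a <- serialize_result(run_query(tbl, q))
  b <- serialize_result(run_query(tbl, q))
  expect_identical(a, b)
})
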