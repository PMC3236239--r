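# In-code fixtures shared across test files.

# Random joined table with the benchmark column schema, including
# missing numeric cells (to exercise three-valued logic), empty
# annotation cells, and deliberate duplicate numeric values (sort-tie
# coverage).
make_random_table <- function(n = 200, seed = 42, na_rate = 0.06) {
  withr::with_seed(seed, {
    vocab <- go_vocabulary()
    rand_go <- function() {
      k <- sample(0:3, 1)
      if (k == 0) return("")
      format_goterms(vocab[sample.int(nrow(vocab), k), c("go_id", "go_name")])
    }
    num_col <- function() {
      v <- round(stats::rlnorm(n, 2, 1.5), 2)   # rounding plants ties
      v[stats::runif(n) < na_rate] <- NA_real_
      v
    }
    df <- data.frame(
      transcript_id = sprintf("T%05d", seq_len(n)),
      sg3 = num_col(), mes1 = num_col(), dmrt1binding = num_col(),
      eye = num_col(),
      description = sample(c("homeobox protein HoxB4", "zinc finger protein",
                             "hypothetical protein", "kinase, putative", ""),
                           n, replace = TRUE),
      goterms = vapply(seq_len(n), function(i) rand_go(), character(1)),
      stringsAsFactors = FALSE)
    as_joined_table(df, "transcript_id", name = "random")
  })
}

# Deterministic 5-row table with hand-checkable values.
make_tiny_table <- function() {
  df <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t4", "t5"),
    sg3  = c(50, 10, 300, 2, 7),
    mes1 = c(4, 20, NA, 2, 7),
    dmrt1binding = c(1, 30, 15, 0, 25),
    eye = c(5, 5, 50, 1, 2),
    description = c("homeobox protein HoxB4", "zinc finger protein 36",
                    "protein, putative", "", "DNA repair protein"),
    goterms = c("GO:0003677|DNA binding",
                "GO:0003700|DNA-binding transcription factor activity;GO:0016563|transcription activator activity",
                "", "GO:0005524|ATP binding", "GO:0003677|DNA binding"),
    stringsAsFactors = FALSE)
  as_joined_table(df, "transcript_id", name = "tiny")
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
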