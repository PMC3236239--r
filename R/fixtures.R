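# Synthetic datasets shaped like the two study designs the query
# language is exercised on: a fish stem-cell deep-sequencing table
# (sg3/mes1/eye expression plus a joinable per-transcript
# transcription-factor binding score) and an endothelial-cell
# microarray table (gfp/notch1/ICAP1 conditions).  Only the planted
# combinatorial structure matters: rows satisfying the benchmark
# queries are constructed, not sampled, so planted counts are exact.

# Small bundled GO vocabulary.  Terms are partitioned so that the text
# predicates used in the benchmark queries are decidable by
# construction: "tf" names contain the substring "transcription
# factor", "activator" names contain "activator", and "neutral" names
# contain neither.
GO_VOCAB <- data.frame(
  go_id = c("GO:0003700", "GO:0000981", "GO:0098531", "GO:0044212",
            "GO:0016563", "GO:0001216", "GO:0010628",
            "GO:0003677", "GO:0005524", "GO:0046872", "GO:0008270",
            "GO:0005515", "GO:0016301", "GO:0004672", "GO:0005634",
            "GO:0005737", "GO:0005886", "GO:0016020", "GO:0007165",
            "GO:0006468", "GO:0055085", "GO:0006355", "GO:0045944",
            "GO:0006915", "GO:0007049", "GO:0008152", "GO:0003824",
            "GO:0005198", "GO:0030154", "GO:0009986"),
  go_name = c(
    "DNA-binding transcription factor activity",
    "DNA-binding transcription factor activity, RNA polymerase II-specific",
    "ligand-modulated transcription factor activity",
    "transcription factor regulatory region DNA binding",
    "transcription activator activity",
    "DNA-binding transcription activator activity",
    "gene expression activator function",
    "DNA binding", "ATP binding", "metal ion binding", "zinc ion binding",
    "protein binding", "kinase activity", "protein kinase activity",
    "nucleus", "cytoplasm", "plasma membrane", "membrane",
    "signal transduction", "protein phosphorylation",
    "transmembrane transport", "regulation of DNA-templated transcription",
    "positive regulation of transcription by RNA polymerase II",
    "apoptotic process", "cell cycle", "metabolic process",
    "catalytic activity", "structural molecule activity",
    "cell differentiation", "cell surface"),
  role = c(rep("tf", 4), rep("activator", 3), rep("neutral", 23)),
  stringsAsFactors = FALSE)

DESCRIPTION_POOL <- c(
  "homeobox protein HoxB4", "homeobox protein HoxA9",
  "paired box protein Pax6", "zinc finger protein 36",
  "heat shock protein 70", "actin, cytoplasmic 1",
  "elongation factor 1-alpha", "ribosomal protein L7",
  "glyceraldehyde-3-phosphate dehydrogenase",
  "fibroblast growth factor receptor 2", "cadherin-1",
  "integrin beta-1", "matrix metalloproteinase 10",
  "endothelial cell-specific molecule 1", "notch homolog 1",
  "microphthalmia-associated protein, putative",
  "uncharacterized protein", "hypothetical protein, partial")

#' The bundled GO vocabulary used by the fixture generators
#'
#' @return data frame with columns `go_id`, `go_name`, `role`.
#' @export
go_vocabulary <- function() GO_VOCAB

#' Write the bundled GO vocabulary as an ID-to-name mapping file
#'
#' @param path output path (two-column TSV, no header), loadable with
#'   [load_go_mapping()].
#' @return `path`, invisibly.
#' @export
write_go_mapping <- function(path) {
  writeLines(paste(GO_VOCAB$go_id, GO_VOCAB$go_name, sep = "\t"), path)
  invisible(path)
}

#' Specify a synthetic fixture
#'
#' @param n_rows number of table rows.
#' @param planted named integer vector of planted row counts; which
#'   names are honoured depends on the generator
#'   (see [generate_medaka_like()], [generate_huvec_like()]).
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(n_rows, planted = c(), seed = 1L) {
  if (length(n_rows) != 1L || is.na(n_rows) || n_rows < 0)
    xq_spec_error("n_rows must be a single non-negative count")
  planted <- if (length(planted)) {
    v <- as.integer(planted)
    names(v) <- names(planted)
    v
  } else integer(0)
  if (length(planted) && (is.null(names(planted)) || any(!nzchar(names(planted)))))
    xq_spec_error("planted counts must be named")
  if (any(planted < 0)) xq_spec_error("planted counts must be non-negative")
  structure(list(n_rows = as.integer(n_rows), planted = planted,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

planted_count <- function(spec, name, default) {
  if (name %in% names(spec$planted)) spec$planted[[name]] else default
}

# Run `expr` under the spec seed without disturbing the caller's RNG.
with_fixture_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

sample_goterms_cell <- function(planted_both) {
  tf  <- GO_VOCAB[GO_VOCAB$role == "tf", ]
  act <- GO_VOCAB[GO_VOCAB$role == "activator", ]
  neu <- GO_VOCAB[GO_VOCAB$role == "neutral", ]
  pick <- function(pool, k) pool[sample.int(nrow(pool), k), , drop = FALSE]
  if (planted_both) {
    anns <- rbind(pick(tf, 1L), pick(act, 1L), pick(neu, sample(0:2, 1L)))
  } else {
    anns <- pick(neu, sample(0:3, 1L))
    u <- stats::runif(1)
    if (u < 0.15) anns <- rbind(pick(tf, 1L), anns)        # tf only
    else if (u < 0.30) anns <- rbind(pick(act, 1L), anns)  # activator only
  }
  format_goterms(anns[, c("go_id", "go_name")])
}

#' Generate a Medaka-style deep-sequencing fixture
#'
#' Produces an expression table (`transcript_id`, `sg3`, `mes1`, `eye`,
#' `description`, `goterms`) and a companion single-score table
#' (`transcript_id`, `dmrt1binding`) joinable on the transcript
#' identifier.  Expression values are drawn from a long-tailed
#' log-normal distribution, as for normalised read counts.  Exactly
#' `planted["tf_activator"]` rows carry both a "transcription factor"
#' and an "activator" GO name (default 25), and exactly
#' `planted["dmrt1_bound"]` of those have `dmrt1binding > 10`
#' (default 10); no other row carries both names, so the planted counts
#' are exact query answers.
#'
#' @param spec a [fixture_spec()]; default
#'   `fixture_spec(500, c(tf_activator = 25, dmrt1_bound = 10), seed = 7)`.
#' @return list with elements `expression` and `binding` (both
#'   [expression_dataset()]s) and `manifest` (planted truth: ids and
#'   counts), class `fixture_set`.
#' @export
generate_medaka_like <- function(spec = fixture_spec(
                                   500L,
                                   c(tf_activator = 25L, dmrt1_bound = 10L),
                                   seed = 7L)) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_rows
  k_both <- planted_count(spec, "tf_activator", min(25L, n))
  k_bound <- planted_count(spec, "dmrt1_bound", min(10L, k_both))
  if (k_both > n)
    xq_spec_error(sprintf("planted tf_activator=%d exceeds n_rows=%d", k_both, n))
  if (k_bound > k_both)
    xq_spec_error(sprintf("planted dmrt1_bound=%d exceeds tf_activator=%d",
                          k_bound, k_both))

  with_fixture_seed(spec$seed, {
    ids <- sprintf("ENSORLT%011d", seq_len(n))
    expr <- data.frame(
      transcript_id = ids,
      sg3  = stats::rlnorm(n, meanlog = 2.0, sdlog = 1.5),
      mes1 = stats::rlnorm(n, meanlog = 2.0, sdlog = 1.5),
      eye  = stats::rlnorm(n, meanlog = 1.5, sdlog = 1.2),
      description = if (n) sample(DESCRIPTION_POOL, n, replace = TRUE)
                    else character(0),
      goterms = character(n),
      stringsAsFactors = FALSE)

    planted_idx <- sort(sample.int(n, k_both))
    is_planted <- seq_len(n) %in% planted_idx
    expr$goterms <- vapply(is_planted, sample_goterms_cell, character(1))

    binding <- data.frame(
      transcript_id = ids,
      dmrt1binding = stats::runif(n, 0, 40),
      stringsAsFactors = FALSE)
    bound_idx <- if (k_bound) sort(sample(planted_idx, k_bound)) else integer(0)
    unbound_idx <- setdiff(planted_idx, bound_idx)
    binding$dmrt1binding[bound_idx]   <- stats::runif(length(bound_idx), 10.5, 60)
    binding$dmrt1binding[unbound_idx] <- stats::runif(length(unbound_idx), 0, 9.5)

    structure(list(
      expression = expression_dataset(expr, "transcript_id", name = "medaka"),
      binding = expression_dataset(binding, "transcript_id",
                                   name = "dmrt1binding"),
      manifest = list(profile = "medaka", n_rows = n, seed = spec$seed,
                      planted_tf_activator = k_both,
                      planted_dmrt1_bound = k_bound,
                      tf_activator_ids = ids[planted_idx],
                      dmrt1_bound_ids = ids[bound_idx])),
      class = "fixture_set")
  })
}

#' Generate a HUVEC-style microarray fixture
#'
#' Produces a probe-level table (`probe_id`, `gfp`, `notch1`, `ICAP1`,
#' `description`, `goterms`) with uniform array-like intensities.
#' Exactly `planted["downregulated"]` rows (default 120) satisfy
#' `gfp > notch1 AND gfp > ICAP1` — for those, both treatment
#' intensities are constructed as sub-unity fractions of the control —
#' and one designated planted row has the strictly largest
#' `gfp/((notch1+ICAP1)/2)` ratio, so it must rank first under the
#' descending fold-change sorter.
#'
#' @param spec a [fixture_spec()]; default
#'   `fixture_spec(400, c(downregulated = 120), seed = 3)`.
#' @return list with elements `expression` and `manifest`
#'   (`planted_ids`, `designated_top_id`), class `fixture_set`.
#' @export
generate_huvec_like <- function(spec = fixture_spec(
                                  400L, c(downregulated = 120L), seed = 3L)) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_rows
  k <- planted_count(spec, "downregulated", min(120L, n))
  if (k > n)
    xq_spec_error(sprintf("planted downregulated=%d exceeds n_rows=%d", k, n))

  with_fixture_seed(spec$seed, {
    ids <- sprintf("A_23_P%06d", sample.int(999999L, n))
    notch1 <- stats::runif(n, 50, 500)
    ICAP1  <- stats::runif(n, 50, 500)
    # non-planted rows: control never exceeds both treatments
    gfp <- pmin(notch1, ICAP1) * stats::runif(n, 0.2, 0.99)

    planted_idx <- sort(sample.int(n, k))
    if (k) {
      g <- stats::runif(k, 100, 800)
      gfp[planted_idx]    <- g
      # fractions bounded away from the designated row's 0.15 so its
      # ratio is strictly the largest
      notch1[planted_idx] <- g * stats::runif(k, 0.35, 0.95)
      ICAP1[planted_idx]  <- g * stats::runif(k, 0.35, 0.95)
      top <- planted_idx[[1]]
      notch1[top] <- gfp[top] * 0.15
      ICAP1[top]  <- gfp[top] * 0.15
    }

    expr <- data.frame(
      probe_id = ids,
      gfp = gfp, notch1 = notch1, ICAP1 = ICAP1,
      description = if (n) sample(DESCRIPTION_POOL, n, replace = TRUE)
                    else character(0),
      goterms = vapply(logical(n), sample_goterms_cell, character(1)),
      stringsAsFactors = FALSE)

    structure(list(
      expression = expression_dataset(expr, "probe_id", name = "huvec"),
      manifest = list(profile = "huvec", n_rows = n, seed = spec$seed,
                      planted_downregulated = k,
                      planted_ids = ids[planted_idx],
                      designated_top_id = if (k) ids[planted_idx[[1]]]
                                          else NA_character_)),
      class = "fixture_set")
  })
}

#' Write a fixture set to disk
#'
#' Writes one TSV per member dataset plus a `manifest.json` recording
#' the planted truth, all consumable by [load_dataset()] /
#' [jsonlite::fromJSON()].
#'
#' @param fixture a `fixture_set`.
#' @param dir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "fixture_set"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    xq_input_error(sprintf("cannot create directory %s", dir))
  paths <- character(0)
  for (part in setdiff(names(fixture), "manifest")) {
    ds <- fixture[[part]]
    p <- file.path(dir, paste0(ds$name, ".tsv"))
    write_dataset(ds, p)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "manifest.json")
  writeLines(as.character(jsonlite::toJSON(fixture$manifest,
                                           auto_unbox = TRUE, pretty = TRUE)),
             mp)
  invisible(c(paths, mp))
}
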