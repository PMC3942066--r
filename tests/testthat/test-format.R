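# A record shaped like the worked labeling example: human hemoglobin
# alpha-2 with gi 450145, rendered with the clock pinned to 2013-05-10.
golden_record <- function() {
  dna <- .rand_fixture_cds(20)
  r <- make_record("NP_000509.1", dna, taxon_id = 9606,
                   organism = "Homo sapiens", gene = "HBA2", gi = "450145")
  r$pcGC <- 65.26
  r
}

test_that("build_annotation populates the guaranteed keys with fallbacks", {
  tax <- toy_taxonomy()
  d <- build_annotation(golden_record(), tax, ordinal = 3L,
                        today = as.Date("2013-05-10"))
  expect_identical(d$ComName, "human")
  expect_identical(d$SciName, "Homo sapiens")
  expect_identical(d$genus, "Homo")
  expect_identical(d$species, "sapiens")
  expect_identical(d$family, "Hominidae")
  expect_identical(d$order, "Primates")
  expect_identical(d$taxID, "9606")
  expect_identical(d$gi, "450145")
  expect_identical(d$acv, "NP_000509.1")
  expect_identical(d$sqNr, "3")
  expect_identical(d$today, "2013-05-10")
  # no common name -> ComName falls back to SciName
  v <- make_record("VVV1.1", "ATGGCATAA", taxon_id = 12242,
                   organism = "Tobacco mosaic virus")
  dv <- build_annotation(v, tax)
  expect_identical(dv$ComName, "Tobacco mosaic virus")
  # rank keys agree with ancestor_at_rank
  expect_identical(d$family,
                   ancestor_at_rank(tax, 9606, "family")$scientific_name)
})

test_that("the five worked label/comment rows render byte-for-byte", {
  tax <- toy_taxonomy()
  d <- build_annotation(golden_record(), tax, ordinal = 1L,
                        today = as.Date("2013-05-10"))
  rows <- list(
    list(">%(ComName)s", "[%(SciName)s]", ">human [Homo sapiens]"),
    list(">%(genus).1 s%(species)s", "gene = %(gene)s",
         ">Hsapiens gene = HBA2"),
    list(">%(gi)s_%(taxID)s", "%(today)s", ">450145_9606 2013-05-10"),
    list(">seq%(sqNr)s", "order = %(order)s", ">seq1 order = Primates"),
    list("%(ComName)s", "%(pcGC)5.2f", "human 65.26"))
  for (row in rows) {
    got <- paste(render_label(row[[1]], d), render_label(row[[2]], d))
    expect_identical(got, row[[3]], label = row[[1]])
  }
})

test_that("render_label handles truncation, floats, escapes and bad input", {
  d <- list(genus = "Homo", species = "sapiens", pcGC = 65.2649, x = "ab")
  expect_identical(render_label(">%(genus).1s%(species)s", d), ">Hsapiens")
  expect_identical(render_label("%(pcGC)5.2f", d), "65.26")
  expect_identical(render_label("%(pcGC)8.1f", d), "    65.3")
  expect_identical(render_label("GC=%(pcGC).0f%%", d), "GC=65%")
  expect_warning(out <- render_label("a%(nope)sb", d), "unknown key")
  expect_identical(out, "ab")
  expect_error(render_label("%(x)q", d), "malformed")
  expect_error(render_label("%(unclosed", d), "malformed")
})

test_that("finalize_labels sanitizes, truncates, then uniquifies in order", {
  expect_identical(finalize_labels(c("human", "human")),
                   c("human", "human_2"))
  expect_identical(finalize_labels("Homo sapiens", charset = "strict"),
                   "Homo_sapiens")
  expect_identical(finalize_labels("Hsapiens", max_length = 5), "Hsapi")
  # truncation applies before uniquification; suffix may exceed the cap
  expect_identical(finalize_labels(c("Hsapiens", "Hsapien"), max_length = 5),
                   c("Hsapi", "Hsapi_2"))
  # a leading FASTA ">" survives strict sanitization
  expect_identical(finalize_labels(">human x", charset = "strict"),
                   ">human_x")
})

test_that("label finalization is injective and order-preserving on random lists", {
  set.seed(31)
  alphabet <- c(letters[1:4], " ", "|", ".")
  for (trial in 1:300) {
    n <- sample(1:40, 1)
    labs <- vapply(seq_len(n), function(i)
      paste(sample(alphabet, sample(1:6, 1), replace = TRUE), collapse = ""),
      "")
    out <- finalize_labels(labs, max_length = sample(c(3L, 8L, NA), 1),
                           charset = sample(c("strict", "permissive"), 1))
    expect_equal(anyDuplicated(out), 0L)
    expect_length(out, n)
    # first occurrences keep their (sanitized, truncated) base form
    expect_true(all(nzchar(out) | !nzchar(labs)))
  }
})

test_that("sequence encodings follow the requested representation", {
  r <- make_record("E1.1", "ATGGCAACGTAA")
  expect_identical(encode_sequence(r, "dna"), "ATGGCAACGTAA")
  expect_identical(encode_sequence(r, "aa"), r$aa_seq)
  expect_identical(wobble_ry("ATGGCA"), "ATRGCR")
  expect_identical(wobble_ry("ATGGCTACN"), "ATRGCYACN")
  expect_equal(nchar(wobble_ry("ATGGCAA")), 7L)  # trailing partial codon kept
  # applying wobble twice equals applying once
  w <- wobble_ry("ATGGCAACGTAA")
  expect_identical(wobble_ry(w), w)
  # whole-sequence purine/pyrimidine recoding
  expect_identical(encode_sequence(r, "ry"), "RYRRYRRYRYRR")
  expect_null(encode_sequence(r, "none"))
  # dna mode on a protein-only passthrough is unavailable
  pt <- resolve_item(parse_selection(">p\nMWWWWWWK")[[1]],
                     expansion_store())$passthrough
  expect_true(is.na(encode_sequence(pt, "dna")))
  expect_identical(encode_sequence(pt, "aa"), "MWWWWWWK")
})

test_that("write_output emits wrapped FASTA and labeled property files", {
  r <- make_record("W1.1", paste(rep("ACGTAC", 30), collapse = ""))
  f <- tempfile()
  write_output(r, ">human", "[Homo sapiens]", mode = "dna", con = f)
  out <- readLines(f)
  expect_identical(out[1], ">human [Homo sapiens]")
  expect_equal(nchar(out[2]), 60L)
  expect_identical(paste(out[-1], collapse = ""), r$dna_seq)
  # property file: label TAB comment, no ">"
  write_output(r, "human", "65.26", mode = "none", con = f)
  expect_identical(readLines(f), "human\t65.26")
  # record without dna in dna mode is skipped with a warning
  pt <- make_record("W2.1", aa_seq = "MKVL")
  expect_warning(n <- write_output(pt, ">x", "", mode = "dna", con = f),
                 "skipped")
  expect_equal(n, 0L)
  # empty input writes empty output without error
  expect_equal(write_output(empty_cds_table(), character(), character(),
                            mode = "dna", con = f), 0L)
})

test_that("format_records composes rendering, finalization and output", {
  tax <- toy_taxonomy()
  recs <- rbind(
    make_record("F1.1", "ATGGCATAA", taxon_id = 9606,
                organism = "Homo sapiens"),
    make_record("F2.1", "ATGGCGTAA", taxon_id = 9606,
                organism = "Homo sapiens"))
  f <- tempfile()
  res <- format_records(recs, tax, preset = "common_name", mode = "dna",
                        today = as.Date("2013-05-10"), con = f)
  expect_identical(res$labels, c("human", "human_2"))
  out <- readLines(f)
  expect_identical(out[1], ">human [Homo sapiens]")
  expect_identical(out[3], ">human_2 [Homo sapiens]")
  # data-provenance property file via templates
  res2 <- format_records(recs, tax, label = "%(family)s",
                         comment = "%(SciName)s\t%(acv)s", mode = "none",
                         con = f)
  out2 <- readLines(f)
  expect_identical(out2[1], "Hominidae\tHomo sapiens\tF1.1")
})
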