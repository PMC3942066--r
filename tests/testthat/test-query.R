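test_that("identifier lists parse one item per line, ignoring blanks", {
  items <- parse_selection("NP_1.1\n\n  NP_2.1  \n")
  expect_length(items, 2L)
  expect_identical(items[[1]]$identifiers, "NP_1.1")
  expect_identical(items[[2]]$identifiers, "NP_2.1")
  expect_equal(vapply(items, `[[`, 1L, "input_ordinal"), 1:2)
  expect_error(parse_selection("   \n \n"), "empty")
})

test_that("FASTA input parses headers, species hints and sequence kinds", {
  txt <- paste(
    ">AAB12345.1 coat protein [Tobacco mosaic virus]",
    "MSYSITTPSQFVFLSSAWADPIELINLCTNALGNQFQTQQARTVVQRQFSEVWKPSPQV",
    ">gi|450145|ref|NP_000509.1| hemoglobin [Homo sapiens]",
    "MVLSPADKTNVKAAWGKVGAHAGEYGAEALERMFLSF",
    ">seq1",
    "atggcaacgt",
    sep = "\n")
  items <- parse_selection(txt)
  expect_length(items, 3L)
  expect_identical(items[[1]]$identifiers, "AAB12345.1")
  expect_identical(items[[1]]$species_hint, "Tobacco mosaic virus")
  expect_identical(items[[1]]$seq_kind, "protein")
  # accession before GI in the pipe form
  expect_identical(items[[2]]$identifiers, c("NP_000509.1", "450145"))
  expect_identical(items[[2]]$species_hint, "Homo sapiens")
  expect_length(items[[3]]$identifiers, 0L)
  expect_identical(items[[3]]$sequence, "ATGGCAACGT")
  expect_identical(items[[3]]$seq_kind, "dna")
  expect_error(parse_selection(">empty\n>seq2\nACGT"), "empty sequence")
})

test_that("wrapped lines and CRLF are tolerated", {
  txt <- ">A.1 x [Homo sapiens]\r\nMKVL\r\nITAG\r\n"
  items <- parse_selection(txt)
  expect_identical(items[[1]]$sequence, "MKVLITAG")
})

test_that("resolution prefers identifiers, then hashes, then passthrough", {
  st <- expansion_store()
  # identifier hit
  it <- parse_selection("HSA00001.1")[[1]]
  res <- resolve_item(it, st)
  expect_identical(res$status, "matched")
  expect_identical(res$matched$protein_accession, "HSA00001.1")
  # sequence hit, case-insensitive, all taxa
  it <- parse_selection(">q\nmkvlitag")[[1]]
  res <- resolve_item(it, st)
  expect_identical(res$status, "matched")
  expect_equal(nrow(res$matched), 4L)
  # species hint restricts the hash match
  it <- parse_selection(">q [Pan troglodytes]\nMKVLITAG")[[1]]
  res <- resolve_item(it, st)
  expect_equal(nrow(res$matched), 1L)
  expect_equal(res$matched$taxon_id, 9598L)
  # common names work as hints too
  it <- parse_selection(">q [human]\nMKVLITAG")[[1]]
  expect_equal(unique(resolve_item(it, st)$matched$taxon_id), 9606L)
})

test_that("novel sequences pass through with hint-derived taxonomy only", {
  st <- expansion_store()
  it <- parse_selection(">novel protein [Mus musculus]\nMWWWWWWK")[[1]]
  res <- resolve_item(it, st)
  expect_identical(res$status, "passthrough")
  pt <- res$passthrough
  expect_true(pt$passthrough)
  expect_equal(pt$taxon_id, 10090L)
  expect_identical(pt$organism, "Mus musculus")
  expect_identical(pt$aa_seq, "MWWWWWWK")
  expect_true(is.na(pt$protein_accession))
  # unmatched hint disables restriction with a warning
  it <- parse_selection(">x [Made-up species]\nMKVLITAG")[[1]]
  expect_warning(res <- resolve_item(it, st), "not found in taxonomy")
  expect_equal(nrow(res$matched), 4L)
})

test_that("identifier-only misses are unresolved, not errors", {
  st <- expansion_store()
  it <- parse_selection("NOPE99.1")[[1]]
  res <- resolve_item(it, st)
  expect_identical(res$status, "unresolved")
  sel <- resolve_selection(parse_selection("HSA00001.1\nNOPE99.1"), st)
  expect_equal(sel$report$matched, 1L)
  expect_equal(sel$report$unresolved, 1L)
  expect_identical(sel$report$unresolved_labels, "NOPE99.1")
})

test_that("resolving the FASTA dump of a stored record re-finds it", {
  st <- fixture_store()
  set.seed(17)
  for (i in sample(store_size(st), 10)) {
    rec <- st$records[i, ]
    fa <- sprintf(">%s some description [%s]\n%s",
                  rec$protein_accession, rec$organism, rec$aa_seq)
    res <- resolve_item(parse_selection(fa)[[1]], st)
    expect_identical(res$status, "matched")
    expect_true(rec$protein_accession %in% res$matched$protein_accession)
    # and via sequence alone (header stripped of identifiers)
    fa2 <- sprintf(">anon [%s]\n%s", rec$organism, tolower(rec$aa_seq))
    res2 <- resolve_item(parse_selection(fa2)[[1]], st)
    expect_identical(res2$status, "matched")
    expect_true(all(res2$matched$taxon_id == rec$taxon_id))
  }
})
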