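# A small hand-written entry exercising join splicing, qualifier
# wrapping, pseudo exclusion and source-feature propagation.
tiny_entry <- function() c(
  "LOCUS       TEST0001                 40 bp    DNA     linear   PRI 10-MAY-2013",
  "DEFINITION  hand-written test entry.",
  "ACCESSION   TEST0001",
  "VERSION     TEST0001.1",
  "FEATURES             Location/Qualifiers",
  "     source          1..40",
  "                     /organism=\"Homo sapiens\"",
  "                     /db_xref=\"taxon:9606\"",
  "     CDS             join(1..6,10..15)",
  "                     /gene=\"tg1\"",
  "                     /protein_id=\"TP_000001.1\"",
  "                     /db_xref=\"GI:450145\"",
  "                     /translation=\"MAT\"",
  "     CDS             20..28",
  "                     /gene=\"tg2\"",
  "                     /pseudo",
  "ORIGIN      ",
  "        1 atggcaacga caacggtacg tacgtacgta cgtacgtacg",
  "//")

test_that("parse_genbank extracts spliced CDS and source annotation from a hand-built entry", {
  recs <- parse_genbank(lines = tiny_entry())
  expect_equal(nrow(recs), 1L)  # pseudo CDS excluded
  r <- recs[1, ]
  # slice-and-concatenate oracle: origin[1:6] + origin[10:15]
  origin <- toupper("atggcaacgacaacggtacgtacgtacgtacgtacgtacg")
  expect_identical(r$dna_seq,
                   paste0(substr(origin, 1, 6), substr(origin, 10, 15)))
  expect_identical(r$aa_seq, "MAT")
  expect_equal(r$taxon_id, 9606L)
  expect_identical(r$organism, "Homo sapiens")
  expect_identical(r$gi, "450145")
  expect_identical(r$source_accession, "TEST0001.1")
  expect_equal(r$source_length, 40L)
  expect_identical(r$entry_date, "2013-05-10")
  expect_equal(r$cds_length, 12L)
  rep <- attr(recs, "report")
  expect_equal(unname(rep["skipped_pseudo"]), 1L)
})

test_that("truncated entries fail loudly, naming the locus", {
  bad <- tiny_entry()
  bad <- bad[-length(bad)]  # drop the // terminator
  expect_error(parse_genbank(lines = bad), "TEST0001")
})

test_that("generated fixtures round-trip field by field against ground truth", {
  gb <- fixture_genbank()
  recs <- suppressWarnings(parse_genbank(gb$path))
  truth <- gb$truth
  keep <- truth[!truth$skip_expected, ]
  expect_gte(nrow(keep), 100L)
  expect_equal(nrow(recs), nrow(keep))
  # pseudo / no-translation exclusions match exactly
  rep <- attr(recs, "report")
  expect_equal(unname(rep["skipped_pseudo"]),
               sum(truth$skip_reason == "pseudo"))
  expect_equal(unname(rep["skipped_no_translation"]),
               sum(truth$skip_reason == "no_translation"))
  m <- merge(as.data.frame(recs), as.data.frame(keep),
             by = "protein_accession", suffixes = c("", ".t"))
  expect_equal(nrow(m), nrow(keep))
  for (col in c("dna_seq", "aa_seq", "gi", "organism", "location",
                "source_accession"))
    expect_identical(m[[col]], m[[paste0(col, ".t")]], label = col)
  for (col in c("taxon_id", "strand", "partial5", "partial3", "cds_length"))
    expect_equal(m[[col]], m[[paste0(col, ".t")]], label = col)
  # derived fields: length conservation and hash of the stored sequence
  expect_equal(m$cds_length, nchar(m$dna_seq))
  expect_true(all(vapply(seq_len(nrow(m)), function(i)
    sequence_md5(m$dna_seq[i], "dna") == m$dna_md5[i], TRUE)))
  # complete CDS with an annotated stop: len(dna) == 3*(len(aa)+1)
  complete <- m[!m$partial5 & !m$partial3, ]
  expect_true(all(complete$cds_length == 3 * (nchar(complete$aa_seq) + 1)))
})

test_that("extraction agrees with an independent GenBank parser (Biopython)", {
  gb <- fixture_genbank()
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  script <- paste(
    "import sys",
    "from Bio import SeqIO",
    "for rec in SeqIO.parse(sys.argv[1], 'genbank'):",
    "    for f in rec.features:",
    "        if f.type != 'CDS' or 'pseudo' in f.qualifiers: continue",
    "        if 'translation' not in f.qualifiers: continue",
    "        acc = f.qualifiers['protein_id'][0]",
    "        tx = [x for x in rec.features if x.type == 'source'][0]",
    "        taxon = [d for d in tx.qualifiers['db_xref'] if d.startswith('taxon:')][0]",
    "        dna = str(f.extract(rec.seq)).upper()",
    "        print('\\t'.join([acc, taxon[6:], f.qualifiers['translation'][0], dna]))",
    sep = "\n")
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  out <- system2(py, c(sf, gb$path), stdout = TRUE)
  expect_gt(length(out), 0)
  bp <- read.table(text = out, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("acc", "taxon", "aa", "dna"))
  recs <- suppressWarnings(parse_genbank(gb$path))
  m <- merge(as.data.frame(recs), bp, by.x = "protein_accession",
             by.y = "acc")
  expect_equal(nrow(m), nrow(recs))
  expect_identical(m$aa_seq, m$aa)
  expect_identical(m$dna_seq, m$dna)
  expect_equal(m$taxon_id, as.integer(m$taxon))
})
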