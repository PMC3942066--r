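# Shared fixtures, built once per test run and memoized.

.fx <- new.env()

# fresh load every call: stores mutate their taxonomy's CDS counters
toy_taxonomy <- function() {
  if (is.null(.fx$taxdir)) {
    d <- file.path(tempdir(), "cdskit-toy-tax")
    make_taxdump(fixture_spec(seed = 1L, n_extra_taxa = 0L), d)
    .fx$taxdir <- d
  }
  load_taxdump(file.path(.fx$taxdir, "nodes.dmp"),
               file.path(.fx$taxdir, "names.dmp"))
}

fixture_genbank <- function() {
  if (is.null(.fx$gb)) {
    path <- file.path(tempdir(), "cdskit-fixture.gb")
    .fx$gb <- make_genbank(fixture_spec(seed = 11L, n_entries = 100L), path)
  }
  .fx$gb
}

fixture_store <- function() {
  if (is.null(.fx$store)) {
    gb <- fixture_genbank()
    st <- cds_store(taxonomy = toy_taxonomy())
    store_put(st, suppressWarnings(parse_genbank(gb$path)))
    .fx$store <- st
  }
  .fx$store
}

# Store for the expansion scenario: one protein in three taxa; the human
# copy has two synonymous CDS; chimp and mouse share one identical CDS.
expansion_store <- function() {
  if (is.null(.fx$exp_store)) {
    aa <- "MKVLITAG"
    dna1 <- "ATGAAAGTACTGATTACCGCAGGTTAA"   # human variant 1
    dna2 <- "ATGAAAGTATTAATCACGGCAGGCTAA"   # human variant 2 (synonymous)
    dna3 <- "ATGAAAGTGCTCATCACCGCTGGATAA"   # chimp and mouse (shared)
    st <- cds_store(taxonomy = toy_taxonomy())
    store_put(st, rbind(
      make_record("HSA00001.1", dna1, aa, taxon_id = 9606,
                  organism = "Homo sapiens"),
      make_record("HSA00002.1", dna2, aa, taxon_id = 9606,
                  organism = "Homo sapiens"),
      make_record("PTR00001.1", dna3, aa, taxon_id = 9598,
                  organism = "Pan troglodytes"),
      make_record("MMU00001.1", dna3, aa, taxon_id = 10090,
                  organism = "Mus musculus")))
    .fx$exp_store <- st
  }
  .fx$exp_store
}

# Brute-force representative oracle: full lexicographic sort over the
# stated criterion tuple, independent of select_representative().
oracle_representative <- function(members, flags, store, taxonomy, config) {
  cand <- which(flags$passes)
  if (length(cand) == 0L) {
    if (config$empty_cluster_policy == "drop") return(NULL)
    kind <- if (config$seq_mode %in% c("aa", "none")) "protein" else "dna"
    seqs <- if (kind == "dna") members$dna_seq else members$aa_seq
    score <- n_unambiguous(seqs, kind)
    best <- which(score == max(score))
    return(members[best[order(members$input_ordinal[best])][1], ])
  }
  mc <- members[cand, ]
  key <- data.frame(
    imp = -species_importance(taxonomy, mc$taxon_id),
    ref = -as.integer(!is.na(mc$is_refseq) & mc$is_refseq),
    rep = -store_representation_count(store, mc$prot_md5),
    cds = -ifelse(is.na(mc$cds_length), 0L, mc$cds_length),
    src = -ifelse(is.na(mc$source_length), 0L, mc$source_length),
    ord = mc$input_ordinal)
  mc[do.call(order, key)[1], ]
}

# Random open reading frame for fabricated records.
.rand_fixture_cds <- function(n_aa) {
  paste0("ATG", paste(sample(c("A", "C", "G", "T"), 3L * n_aa,
                             replace = TRUE), collapse = ""), "TAA")
}

# Path of the installed CLI script.
cdskit_cli <- function() {
  system.file("scripts", "cdskit", package = "cdskit")
}
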