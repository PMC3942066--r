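#' Sequence hashing, composition and accession helpers
#'
#' Small pure functions shared by the ingest, store and pipeline layers.
#'
#' @name seq-utils
NULL

# 20 standard amino acids; anything else (X, B, Z, U, O, ...) is ambiguous.
.STD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' MD5 digest of a sequence
#'
#' Sequences are compared case-insensitively but otherwise exactly, so the
#' digest is taken over the uppercased, whitespace-stripped sequence.
#' Terminal/internal stop characters (`*`) are stripped from protein
#' sequences before hashing so that translations with and without an
#' annotated stop hash identically.
#'
#' @param seq Single character string, DNA or protein.
#' @param kind `"dna"` or `"protein"`; controls `*` stripping only.
#' @return 32-character lowercase hex digest.
#' @export
#' @examples
#' sequence_md5("acgt") == sequence_md5("ACGT")
sequence_md5 <- function(seq, kind = c("protein", "dna")) {
  kind <- match.arg(kind)
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("sequence_md5: empty or missing sequence")
  s <- toupper(gsub("[[:space:]]", "", seq))
  if (kind == "protein") s <- gsub("\\*", "", s)
  if (!nzchar(s)) stop("sequence_md5: sequence empty after normalization")
  digest::digest(s, algo = "md5", serialize = FALSE)
}

#' Percent GC content
#'
#' 100 * (G + C + S) / length. `S` is the IUPAC strong code (G or C) and
#' counts toward the numerator; all other ambiguity codes count only in the
#' denominator.
#'
#' @param dna Single nucleotide string.
#' @return Percent in \[0, 100\].
#' @export
percent_gc <- function(dna) {
  if (length(dna) != 1L || is.na(dna) || !nzchar(dna))
    stop("percent_gc: empty or missing sequence")
  s <- toupper(dna)
  n <- nchar(s)
  gc <- n - nchar(gsub("[GCS]", "", s))
  100 * gc / n
}

#' RefSeq membership from accession shape
#'
#' RefSeq accessions carry an underscore between a letter prefix and the
#' numeric body (`NP_`, `XP_`, `YP_`, `WP_`, `NM_`, ...).
#'
#' @param accession Character vector of accessions.
#' @return Logical vector.
#' @export
is_refseq <- function(accession) {
  grepl("^[A-Za-z]+_[0-9]+(\\.[0-9]+)?$", accession)
}

#' Accession stem (version stripped)
#'
#' @param accession Character vector, e.g. `"NP_000509.1"`.
#' @return The accession without its trailing `.N` version.
#' @export
accession_stem <- function(accession) {
  sub("\\.[0-9]+$", "", accession)
}

#' Ambiguity tests
#'
#' A DNA sequence is ambiguous when any character falls outside `A`, `C`,
#' `G`, `T`; a protein sequence when any character falls outside the 20
#' standard amino acids (stop `*` is ignored).
#'
#' @param seq Character vector of sequences (`NA` returns `NA`).
#' @return Logical vector.
#' @export
dna_is_ambiguous <- function(seq) {
  ifelse(is.na(seq), NA, grepl("[^ACGT]", toupper(seq)))
}

#' @rdname dna_is_ambiguous
#' @export
aa_is_ambiguous <- function(seq) {
  ifelse(is.na(seq), NA,
         grepl(sprintf("[^%s]", paste(.STD_AA, collapse = "")),
               gsub("\\*", "", toupper(seq))))
}

#' Count of non-ambiguous residues
#'
#' @param seq Character vector.
#' @param kind `"dna"` or `"protein"`.
#' @return Integer vector; `NA` sequences give 0.
#' @export
n_unambiguous <- function(seq, kind = c("protein", "dna")) {
  kind <- match.arg(kind)
  pat <- if (kind == "dna") "[^ACGT]" else
    sprintf("[^%s]", paste(.STD_AA, collapse = ""))
  out <- integer(length(seq))
  ok <- !is.na(seq)
  out[ok] <- nchar(gsub(pat, "", toupper(seq[ok])))
  out
}

#' Reverse complement of a nucleotide string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] handling IUPAC
#' ambiguity codes.
#'
#' @param dna Single nucleotide string.
#' @return Reverse-complemented string, same case policy as input (upper).
#' @export
reverse_complement <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(dna))))
}

#' Guess the alphabet of a raw sequence
#'
#' Sequences with >= 90% of characters in `A`, `C`, `G`, `T`, `N`, `U` are
#' called DNA, otherwise protein.
#'
#' @param seq Single sequence string.
#' @return `"dna"` or `"protein"`.
#' @export
guess_seq_kind <- function(seq) {
  s <- toupper(gsub("[[:space:]]", "", seq))
  if (!nzchar(s)) return("unknown")
  frac <- nchar(gsub("[^ACGTNU]", "", s)) / nchar(s)
  if (frac >= 0.9) "dna" else "protein"
}
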