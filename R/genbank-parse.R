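#' Parse GenBank flat files into CDS records
#'
#' Reads a release-format GenBank flat file (`LOCUS` ... `//`) and returns
#' one row per CDS feature that carries a `/translation` qualifier.
#' Pseudo genes (`/pseudo`) and CDS without translation are skipped and
#' counted. Source-feature annotation (organism, `taxon:` db_xref, entry
#' length, entry date) is attached to every CDS of the entry. The spliced
#' CDS nucleotide sequence is extracted from the `ORIGIN` block on the
#' coding strand, and MD5 hashes, GC content and 5'/3' completeness flags
#' are computed.
#'
#' @param path Path to a GenBank flat file (or a character vector of
#'   already-read lines via `lines =`).
#' @param lines Optional character vector of file lines; overrides `path`.
#' @return A [data.table::data.table] of CDS records (class
#'   `cds_table`), with the ingest report in attribute `"report"`:
#'   counts of entries read, CDS kept, pseudo skipped, no-translation
#'   skipped, entries skipped for missing ORIGIN.
#' @export
parse_genbank <- function(path = NULL, lines = NULL) {
  if (is.null(lines)) lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  term <- grep("^//\\s*$", lines)
  starts <- grep("^LOCUS ", lines)
  if (length(starts) == 0L) stop("parse_genbank: no LOCUS line found")
  if (length(term) < length(starts)) {
    locus <- sub("^LOCUS +(\\S+).*", "\\1", lines[starts[length(term) + 1L]])
    stop("parse_genbank: truncated entry (no '//' terminator) at locus ", locus)
  }

  report <- c(entries = 0L, cds_kept = 0L, skipped_pseudo = 0L,
              skipped_no_translation = 0L, skipped_no_origin = 0L)
  recs <- list()
  prev <- 0L
  for (k in seq_along(starts)) {
    entry <- lines[(prev + 1L):term[k]]
    prev <- term[k]
    report["entries"] <- report["entries"] + 1L
    parsed <- .parse_entry(entry)
    report["skipped_pseudo"] <- report["skipped_pseudo"] + parsed$n_pseudo
    report["skipped_no_translation"] <-
      report["skipped_no_translation"] + parsed$n_no_transl
    if (parsed$no_origin) {
      warning("parse_genbank: entry ", parsed$locus,
              " has no ORIGIN sequence; skipped", call. = FALSE)
      report["skipped_no_origin"] <- report["skipped_no_origin"] + 1L
      next
    }
    report["cds_kept"] <- report["cds_kept"] + nrow(parsed$records)
    recs[[length(recs) + 1L]] <- parsed$records
  }
  out <- data.table::rbindlist(recs, use.names = TRUE, fill = TRUE)
  if (nrow(out) == 0L) out <- empty_cds_table()
  data.table::setattr(out, "report", report)
  data.table::setattr(out, "class", c("cds_table", class(out)))
  out[]
}

#' An empty CDS record table with the full column set
#' @return Zero-row `data.table` with the canonical CDS record columns.
#' @export
empty_cds_table <- function() {
  data.table::data.table(
    protein_accession = character(), accession_stem = character(),
    gi = character(), source_accession = character(),
    taxon_id = integer(), organism = character(),
    gene = character(), product = character(),
    locus_tag = character(), note = character(),
    codon_start = integer(), transl_table = integer(),
    location = character(), strand = integer(),
    dna_seq = character(), aa_seq = character(),
    dna_md5 = character(), prot_md5 = character(),
    partial5 = logical(), partial3 = logical(),
    is_refseq = logical(), cds_length = integer(),
    source_length = integer(), pcGC = numeric(),
    entry_date = character(), passthrough = logical(),
    orig_label = character())
}

# Parse a single LOCUS..// block (character vector of lines).
.parse_entry <- function(entry) {
  locus_line <- entry[startsWith(entry, "LOCUS")]
  locus_tok <- strsplit(trimws(sub("^LOCUS", "", locus_line[1])), "\\s+")[[1]]
  locus <- locus_tok[1]
  src_len <- suppressWarnings(as.integer(locus_tok[2]))
  date_tok <- locus_tok[length(locus_tok)]
  entry_date <- .parse_gb_date(date_tok)

  ver_line <- entry[startsWith(entry, "VERSION")]
  src_acc <- if (length(ver_line)) {
    strsplit(trimws(sub("^VERSION", "", ver_line[1])), "\\s+")[[1]][1]
  } else {
    acc_line <- entry[startsWith(entry, "ACCESSION")]
    if (length(acc_line)) strsplit(trimws(sub("^ACCESSION", "", acc_line[1])),
                                   "\\s+")[[1]][1] else locus
  }

  feat_i <- which(startsWith(entry, "FEATURES"))
  origin_i <- which(startsWith(entry, "ORIGIN"))
  origin <- NULL
  if (length(origin_i)) {
    seq_lines <- entry[(origin_i[1] + 1L):(length(entry) - 1L)]
    origin <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (!nzchar(origin)) origin <- NULL
  }

  features <- if (length(feat_i)) {
    end_i <- if (length(origin_i)) origin_i[1] - 1L else length(entry) - 1L
    .parse_features(entry[(feat_i[1] + 1L):end_i])
  } else list()

  # source-feature context
  organism <- NA_character_; taxon_id <- NA_integer_
  for (f in features) {
    if (f$key == "source") {
      if (!is.null(f$qual$organism)) organism <- f$qual$organism
      tx <- grep("^taxon:", unlist(f$qual[names(f$qual) == "db_xref"]),
                 value = TRUE)
      if (length(tx)) taxon_id <- as.integer(sub("^taxon:", "", tx[1]))
      break
    }
  }

  n_pseudo <- 0L; n_no_transl <- 0L
  rows <- list()
  for (f in features) {
    if (f$key != "CDS") next
    if (!is.null(f$qual$pseudo) || !is.null(f$qual$pseudogene)) {
      n_pseudo <- n_pseudo + 1L; next
    }
    aa <- f$qual$translation
    if (is.null(aa) || !nzchar(aa)) { n_no_transl <- n_no_transl + 1L; next }
    if (is.null(origin)) next  # counted at entry level
    loc <- parse_location(f$loc)
    dna <- splice_sequence(loc, origin)
    pf <- partial_flags(loc)
    aa <- toupper(gsub("[[:space:]]", "", aa))
    acc <- f$qual$protein_id %||% paste0(locus, "_CDS", length(rows) + 1L)
    gi <- {
      gx <- grep("^GI:", unlist(f$qual[names(f$qual) == "db_xref"]),
                 value = TRUE)
      if (length(gx)) sub("^GI:", "", gx[1]) else NA_character_
    }
    rows[[length(rows) + 1L]] <- data.table::data.table(
      protein_accession = acc, accession_stem = accession_stem(acc),
      gi = gi, source_accession = src_acc,
      taxon_id = taxon_id, organism = organism,
      gene = f$qual$gene %||% NA_character_,
      product = f$qual$product %||% NA_character_,
      locus_tag = f$qual$locus_tag %||% NA_character_,
      note = f$qual$note %||% NA_character_,
      codon_start = as.integer(f$qual$codon_start %||% 1L),
      transl_table = as.integer(f$qual$transl_table %||% 1L),
      location = f$loc, strand = loc$strand,
      dna_seq = dna, aa_seq = aa,
      dna_md5 = sequence_md5(dna, "dna"),
      prot_md5 = sequence_md5(aa, "protein"),
      partial5 = unname(pf["partial5"]), partial3 = unname(pf["partial3"]),
      is_refseq = is_refseq(acc),
      cds_length = nchar(dna),
      source_length = if (is.na(src_len)) nchar(origin) else src_len,
      pcGC = percent_gc(dna), entry_date = entry_date,
      passthrough = FALSE, orig_label = NA_character_)
  }
  records <- if (length(rows)) data.table::rbindlist(rows) else empty_cds_table()
  list(locus = locus, records = records, n_pseudo = n_pseudo,
       n_no_transl = n_no_transl,
       no_origin = is.null(origin) &&
         any(vapply(features, function(f) f$key == "CDS", TRUE)))
}

# Parse the FEATURES block: key at column 6, qualifiers/continuations at 22.
.parse_features <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  is_key <- grepl("^ {5}\\S", lines)
  feats <- list()
  cur <- NULL
  flush <- function(cur, feats) { if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur; feats }
  for (ln in lines) {
    if (grepl("^ {5}\\S", ln)) {
      feats <- flush(cur, feats)
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      cur <- list(key = tok[1], loc = paste(tok[-1], collapse = ""),
                  raw_quals = character())
    } else if (!is.null(cur)) {
      cur$raw_quals <- c(cur$raw_quals, trimws(ln))
    }
  }
  feats <- flush(cur, feats)
  lapply(feats, function(f) {
    # location may continue onto lines before the first qualifier
    qstart <- which(startsWith(f$raw_quals, "/"))
    if (length(qstart) == 0L) qstart <- length(f$raw_quals) + 1L else qstart <- qstart[1]
    if (qstart > 1L)
      f$loc <- paste0(f$loc, paste(f$raw_quals[seq_len(qstart - 1L)], collapse = ""))
    f$qual <- .parse_qualifiers(
      if (qstart <= length(f$raw_quals)) f$raw_quals[qstart:length(f$raw_quals)]
      else character())
    f$raw_quals <- NULL
    f
  })
}

# Fold continuation lines into their qualifier, then split /key="value".
.parse_qualifiers <- function(qlines) {
  if (length(qlines) == 0L) return(list())
  grp <- cumsum(startsWith(qlines, "/"))
  qual <- list()
  for (g in unique(grp)) {
    chunk <- qlines[grp == g]
    # translations wrap without spaces; other qualifiers keep a space
    joined <- if (grepl("^/translation=", chunk[1]))
      paste(chunk, collapse = "") else paste(chunk, collapse = " ")
    m <- regmatches(joined, regexec("^/([A-Za-z_]+)(=(.*))?$", joined))[[1]]
    if (length(m) == 0L) next
    key <- m[2]
    val <- if (nzchar(m[3])) m[4] else TRUE  # flag qualifier like /pseudo
    if (is.character(val)) val <- gsub("^\"|\"$", "", val)
    qual[[length(qual) + 1L]] <- stats::setNames(list(val), key)
  }
  # keep duplicates (db_xref repeats)
  do.call(c, qual)
}

.parse_gb_date <- function(tok) {
  d <- try(as.Date(tok, format = "%d-%b-%Y"), silent = TRUE)
  if (inherits(d, "try-error") || is.na(d)) NA_character_ else format(d, "%Y-%m-%d")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
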