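#' User selection parsing and resolution
#'
#' User input is either a list of unique identifiers, one per line, or
#' FASTA (DNA or protein). FASTA title lines in NCBI style yield candidate
#' identifiers, and a species name in square brackets becomes a taxonomy
#' hint used to restrict hash matches. When no database match exists a
#' sequence is carried through as provided, without annotation except the
#' hinted taxonomy.
#'
#' @name query-resolver
NULL

#' Parse a selection (identifier list or FASTA) into selector items
#'
#' Input whose first non-blank character is `>` parses as FASTA (wrapped
#' lines and CRLF tolerated); otherwise one identifier per line. NCBI
#' headers of the forms `gi|N|db|ACC.V|...` and `ACC.V description
#' [Species name]` yield identifiers in accession-before-GI order and the
#' species hint.
#'
#' @param text Character scalar (whole input) or vector of lines.
#' @return List of selector items: `raw_label`, `identifiers` (character
#'   vector), `sequence` (or `NA`), `seq_kind`, `species_hint` (or `NA`),
#'   `input_ordinal`.
#' @export
parse_selection <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L) stop("parse_selection: empty input")

  if (startsWith(trimws(nonblank[1]), ">")) {
    .parse_fasta_items(lines)
  } else {
    ids <- trimws(nonblank)
    lapply(seq_along(ids), function(i)
      list(raw_label = ids[i], identifiers = ids[i],
           sequence = NA_character_, seq_kind = "unknown",
           species_hint = NA_character_, input_ordinal = i))
  }
}

.parse_fasta_items <- function(lines) {
  hdr_i <- which(startsWith(trimws(lines), ">"))
  items <- vector("list", length(hdr_i))
  bounds <- c(hdr_i, length(lines) + 1L)
  for (k in seq_along(hdr_i)) {
    hdr <- sub("^\\s*>", "", lines[hdr_i[k]])
    body <- if (bounds[k + 1L] - 1L > bounds[k])
      lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)] else character()
    seq <- toupper(gsub("[[:space:]]", "", paste(body, collapse = "")))
    if (!nzchar(seq))
      stop("parse_selection: FASTA record with empty sequence: '>", hdr, "'")
    items[[k]] <- c(.parse_ncbi_header(hdr),
                    list(sequence = seq, seq_kind = guess_seq_kind(seq),
                         input_ordinal = k))
  }
  items
}

# Extract identifiers and [Species] hint from a FASTA title line.
.parse_ncbi_header <- function(hdr) {
  hdr <- trimws(hdr)
  hint <- NA_character_
  m <- regmatches(hdr, regexec("\\[([^][]+)\\]\\s*$", hdr))[[1]]
  if (length(m)) hint <- m[2]
  accs <- character(); gis <- character()
  if (grepl("\\|", hdr)) {
    tok <- strsplit(strsplit(hdr, "\\s+")[[1]][1], "|", fixed = TRUE)[[1]]
    for (i in seq_along(tok)) {
      if (tolower(tok[i]) == "gi" && i < length(tok) &&
          grepl("^[0-9]+$", tok[i + 1L]))
        gis <- c(gis, tok[i + 1L])
      else if (grepl("^[A-Za-z]+_?[0-9]+\\.[0-9]+$", tok[i]))
        accs <- c(accs, tok[i])
    }
  } else {
    # an accession-shaped token: versioned, or uppercase prefix + >= 5
    # digits (plain local names like "seq1" must not be mistaken for one)
    first <- strsplit(hdr, "\\s+")[[1]][1]
    if (grepl("^[A-Za-z]+_?[0-9]+\\.[0-9]+$", first) ||
        grepl("^[A-Z]+_?[0-9]{5,}$", first)) accs <- first
    else if (grepl("^[0-9]+$", first)) gis <- first
  }
  list(raw_label = hdr, identifiers = c(accs, gis), species_hint = hint)
}

#' Resolve one selector item against the store
#'
#' Identifiers are tried in order via [store_get_by_id()]. On failure,
#' when a sequence is present it is hashed and looked up in the protein
#' then the DNA hash index, restricted to the hinted species when the
#' hint resolves in the taxonomy. On total failure with a sequence a
#' passthrough record is emitted carrying only the label, the sequence
#' and hint-derived taxonomy; identifier-only items that fail are
#' reported unresolved. Failures are data, not errors.
#'
#' @param item A selector item from [parse_selection()].
#' @param store A `cds_store`.
#' @param taxonomy A `taxonomy_db` (defaults to the store's).
#' @return List with `item`, `matched` (CDS `data.table`, zero rows when
#'   none), `passthrough` (one-row `data.table` or `NULL`), `status`
#'   (`"matched"`, `"passthrough"`, `"unresolved"`).
#' @export
resolve_item <- function(item, store, taxonomy = store$taxonomy) {
  matched <- empty_cds_table()
  for (id in item$identifiers) {
    hit <- store_get_by_id(store, id)
    if (!is.null(hit)) { matched <- hit; break }
  }
  hint_taxon <- NA_integer_
  if (!is.na(item$species_hint) && !is.null(taxonomy)) {
    hint_taxon <- taxon_by_name(taxonomy, item$species_hint)
    if (is.na(hint_taxon))
      warning("resolve: species hint '", item$species_hint,
              "' not found in taxonomy; restriction disabled", call. = FALSE)
  }
  if (nrow(matched) == 0L && !is.na(item$sequence)) {
    restrict <- if (is.na(hint_taxon)) NULL else hint_taxon
    for (kind in c("protein", "dna")) {
      md5 <- sequence_md5(item$sequence, kind)
      matched <- store_get_by_hash(store, md5, kind, taxon_id = restrict)
      if (nrow(matched) > 0L) break
    }
  }
  if (nrow(matched) > 0L)
    return(list(item = item, matched = matched, passthrough = NULL,
                status = "matched"))
  if (!is.na(item$sequence)) {
    pt <- .passthrough_record(item, hint_taxon,
                              if (is.null(taxonomy)) NULL else taxonomy)
    return(list(item = item, matched = matched, passthrough = pt,
                status = "passthrough"))
  }
  list(item = item, matched = matched, passthrough = NULL,
       status = "unresolved")
}

.passthrough_record <- function(item, hint_taxon, taxonomy) {
  r <- empty_cds_table()[1, ]  # one row of NAs with right types
  seq <- item$sequence
  kind <- item$seq_kind
  r$passthrough <- TRUE
  r$orig_label <- item$raw_label
  r$taxon_id <- hint_taxon
  if (!is.na(hint_taxon) && !is.null(taxonomy))
    r$organism <- .tax_node(taxonomy, hint_taxon)$scientific_name
  if (kind == "dna") {
    r$dna_seq <- seq
    r$dna_md5 <- sequence_md5(seq, "dna")
    r$cds_length <- nchar(seq)
    r$pcGC <- percent_gc(seq)
  } else {
    r$aa_seq <- seq
    r$prot_md5 <- sequence_md5(seq, "protein")
  }
  r$partial5 <- FALSE
  r$partial3 <- FALSE
  r$is_refseq <- FALSE
  r
}

#' Resolve a full selection
#'
#' @param items List of selector items.
#' @param store A `cds_store`.
#' @param taxonomy Optional `taxonomy_db`.
#' @return List with `records` (ordered CDS `data.table`, one block per
#'   matched/passthrough item, column `input_ordinal` added) and
#'   `report` (resolved / passthrough / unresolved counts plus the
#'   unresolved labels).
#' @export
resolve_selection <- function(items, store, taxonomy = store$taxonomy) {
  blocks <- list()
  unresolved <- character()
  n_matched <- 0L; n_pass <- 0L
  for (item in items) {
    res <- resolve_item(item, store, taxonomy)
    if (res$status == "matched") {
      b <- data.table::copy(res$matched)
      n_matched <- n_matched + 1L
    } else if (res$status == "passthrough") {
      b <- res$passthrough
      n_pass <- n_pass + 1L
    } else {
      unresolved <- c(unresolved, item$raw_label)
      next
    }
    b$input_ordinal <- item$input_ordinal
    b$orig_label <- item$raw_label
    blocks[[length(blocks) + 1L]] <- b
  }
  records <- if (length(blocks))
    data.table::rbindlist(blocks, use.names = TRUE, fill = TRUE)
  else cbind(empty_cds_table(), data.table::data.table(input_ordinal = integer()))
  list(records = records,
       report = list(items = length(items), matched = n_matched,
                     passthrough = n_pass, unresolved = length(unresolved),
                     unresolved_labels = unresolved))
}
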