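#' Sequence labeling and output formatting
#'
#' Renders selected records as labeled FASTA (protein, DNA, or wobble
#' recodings) or as labeled property files for tree annotation, using
#' preset labels or printf-style templates over a per-record annotation
#' dictionary, with character sanitization, length control and
#' uniqueness.
#'
#' @name format-engine
NULL

#' Build the annotation dictionary for one record
#'
#' Guaranteed keys: `acv` (versioned protein accession), `gi`, `taxID`,
#' `SciName`, `ComName` (falls back to `SciName` when the taxon has no
#' common name), `gene`, `product`, `genus`, `species` (the specific
#' epithet, i.e. the species name with its leading genus stripped),
#' every taxonomic rank present in the lineage as its own key (`order`,
#' `family`, ...), `sqNr` (1-based output ordinal), `today` (ISO date,
#' injectable for reproducible output), `pcGC`, `length` (protein length
#' when an amino acid sequence exists, else CDS length), and `origLabel`
#' (the user's input label). Absent values render as empty strings.
#'
#' @param record One-row CDS `data.table`.
#' @param taxonomy A `taxonomy_db` or `NULL`.
#' @param ordinal 1-based position in the output.
#' @param today Date used for the `today` key (default current date).
#' @return Named list (the template dictionary).
#' @export
build_annotation <- function(record, taxonomy = NULL, ordinal = 1L,
                             today = Sys.Date()) {
  chr <- function(x) if (is.null(x) || length(x) == 0L || is.na(x)) "" else
    as.character(x)
  d <- list(
    acv = chr(record$protein_accession),
    gi = chr(record$gi),
    taxID = chr(record$taxon_id),
    SciName = chr(record$organism),
    ComName = "",
    gene = chr(record$gene),
    product = chr(record$product),
    locus_tag = chr(record$locus_tag),
    note = chr(record$note),
    genus = "", species = "",
    sqNr = as.character(ordinal),
    today = format(as.Date(today), "%Y-%m-%d"),
    pcGC = if (is.na(record$pcGC)) "" else record$pcGC,
    length = if (!is.na(record$aa_seq)) nchar(record$aa_seq)
             else if (!is.na(record$dna_seq)) nchar(record$dna_seq) else "",
    origLabel = chr(record$orig_label))
  tid <- record$taxon_id
  if (!is.null(taxonomy) && !is.na(tid) && tid %in% taxonomy$nodes$tax_id) {
    node <- .tax_node(taxonomy, tid)
    d$SciName <- chr(node$scientific_name)
    d$ComName <- chr(node$common_name)
    lin <- lineage(taxonomy, tid)
    ranked <- lin[!is.na(lin$rank) & lin$rank != "no rank", ]
    for (i in seq_len(nrow(ranked)))
      d[[ranked$rank[i]]] <- chr(ranked$scientific_name[i])
    if (!is.null(d$genus) && nzchar(d$genus)) {
      sp_node <- ancestor_at_rank(taxonomy, tid, "species")
      sp <- if (is.null(sp_node)) d$SciName else chr(sp_node$scientific_name)
      d$species <- sub(paste0("^", d$genus, " "), "", sp)
    }
  }
  if (!nzchar(d$ComName)) d$ComName <- d$SciName
  d
}

#' Render a printf-style template against a dictionary
#'
#' Supports the conversions `%(key)s`, `%(key).Ns` (truncate to N
#' characters) and `%(key)M.Nf` (fixed-point float, width M, N
#' decimals). Unknown keys render as the empty string with a warning;
#' a malformed conversion is an error naming its position. `%%` renders
#' a literal percent.
#'
#' @param template Template string.
#' @param dict Named list from [build_annotation()].
#' @return Rendered string.
#' @export
#' @examples
#' render_label(">%(genus).1s%(species)s",
#'              list(genus = "Homo", species = "sapiens"))
render_label <- function(template, dict) {
  s <- gsub("%%", "\01", template, fixed = TRUE)
  out <- ""
  pos <- 1L
  n <- nchar(s)
  while (pos <= n) {
    rest <- substring(s, pos)
    hit <- regexpr("%\\(", rest)
    if (hit == -1L) { out <- paste0(out, rest); break }
    out <- paste0(out, substring(rest, 1L, hit - 1L))
    m <- regmatches(
      substring(rest, hit),
      regexec("^%\\(([^)]*)\\)(-?[0-9]*(\\.[0-9]+)?) ?([sf])",
              substring(rest, hit)))[[1]]
    if (length(m) == 0L)
      stop("render_label: malformed conversion at position ",
           pos + hit - 1L, " in '", template, "'")
    key <- m[2]; spec <- m[3]; conv_ch <- m[5]
    val <- dict[[key]]
    if (is.null(val)) {
      warning("render_label: unknown key '", key, "' rendered empty",
              call. = FALSE)
      val <- ""
    }
    piece <- if (conv_ch == "f") {
      v <- suppressWarnings(as.numeric(val))
      if (is.na(v)) "" else sprintf(paste0("%", spec, "f"), v)
    } else {
      sprintf(paste0("%", spec, "s"), as.character(val))
    }
    out <- paste0(out, piece)
    pos <- pos + hit - 1L + nchar(m[1])
  }
  gsub("\01", "%", out, fixed = TRUE)
}

#' Label presets
#'
#' Named template pairs for the common labeling choices: species common
#' name (the default; scientific name in the comment), identifiers,
#' species name, gene name, or the original uploaded label.
#'
#' @param preset Preset name.
#' @return List with `label` and `comment` templates.
#' @export
label_preset <- function(preset = c("common_name", "identifiers", "species",
                                    "gene", "original")) {
  switch(match.arg(preset),
         common_name = list(label = "%(ComName)s", comment = "[%(SciName)s]"),
         identifiers = list(label = "%(acv)s", comment = ""),
         species = list(label = "%(SciName)s", comment = ""),
         gene = list(label = "%(gene)s", comment = ""),
         original = list(label = "%(origLabel)s", comment = ""))
}

#' Sanitize, truncate and uniquify labels
#'
#' Under the strict charset policy every character outside
#' `[A-Za-z0-9_.-]` maps to `_` (a leading `>` FASTA marker, when
#' present, is preserved). Truncation to `max_length` applies before
#' uniquification; duplicate labels get `_2`, `_3`, ... appended (the
#' first occurrence is unchanged), and the suffix may exceed
#' `max_length`.
#'
#' @param labels Character vector in output order.
#' @param max_length Optional integer label length cap.
#' @param charset `"permissive"` (no substitution) or `"strict"`.
#' @return Character vector of unique labels, order preserved.
#' @export
finalize_labels <- function(labels, max_length = NULL,
                            charset = c("permissive", "strict")) {
  charset <- match.arg(charset)
  out <- vapply(labels, function(l) {
    lead <- startsWith(l, ">")
    if (lead) l <- substring(l, 2L)
    if (charset == "strict") l <- gsub("[^A-Za-z0-9_.-]", "_", l)
    if (!is.null(max_length) && !is.na(max_length) && nchar(l) > max_length)
      l <- substr(l, 1L, max_length)
    if (lead) paste0(">", l) else l
  }, "", USE.NAMES = FALSE)
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(out)) {
    base <- out[i]
    k <- get0(base, envir = seen, ifnotfound = 0L)
    assign(base, k + 1L, envir = seen)
    if (k > 0L) {
      repeat {
        cand <- paste0(base, "_", k + 1L)
        if (is.null(get0(cand, envir = seen))) break
        k <- k + 1L
      }
      assign(cand, 1L, envir = seen)
      out[i] <- cand
    }
  }
  out
}

#' Encode a record's sequence for output
#'
#' Modes: `aa` (amino acid), `dna` (spliced CDS), `wobble_ry` (third
#' codon position recoded to R for purines, Y for pyrimidines, N
#' otherwise; positions 1-2 untouched), `ry` (whole-sequence
#' purine/pyrimidine recoding, an extension of the wobble mode), `none`
#' (no sequence; property-file output). DNA modes on a record without a
#' CDS return `NA` (caller skips with a warning).
#'
#' @param record One-row CDS `data.table`.
#' @param mode Sequence mode string.
#' @return Sequence string, `NA` (unavailable), or `NULL` (mode none).
#' @export
encode_sequence <- function(record,
                            mode = c("dna", "aa", "wobble_ry", "ry", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(NULL)
  if (mode == "aa") {
    return(if (is.na(record$aa_seq)) NA_character_ else record$aa_seq)
  }
  if (is.na(record$dna_seq)) return(NA_character_)
  switch(mode,
         dna = record$dna_seq,
         wobble_ry = wobble_ry(record$dna_seq),
         ry = .ry_recode(record$dna_seq))
}

#' Third-codon-position R/Y recoding
#'
#' @param dna Nucleotide string (codon frame starting at position 1).
#' @return String of equal length with every third base replaced by `R`
#'   (A/G), `Y` (C/T) or `N`.
#' @export
wobble_ry <- function(dna) {
  ch <- strsplit(toupper(dna), "")[[1]]
  third <- seq(3L, length(ch), by = 3L)
  # R/Y map to themselves so the recoding is idempotent
  ch[third] <- ifelse(ch[third] %in% c("A", "G", "R"), "R",
                      ifelse(ch[third] %in% c("C", "T", "Y"), "Y", "N"))
  paste(ch, collapse = "")
}

.ry_recode <- function(dna) {
  chartr("AGRCTY", "RRRYYY",
         gsub("[^AGRCTY]", "N", toupper(dna)))
}

#' Write labeled sequences or a labeled property file
#'
#' Sequence modes write FASTA: the header is the label, a single space
#' and the comment when nonempty (a `>` is prepended when the label does
#' not supply one), with the sequence wrapped at 60 columns. Mode
#' `none` writes one `label<TAB>comment` line per record — a labeled
#' property file for tree relabeling/annotation tools.
#'
#' @param records CDS `data.table` of selected representatives.
#' @param labels,comments Character vectors, one per record.
#' @param mode Sequence mode (see [encode_sequence()]).
#' @param con Connection, file path, or `""` for stdout.
#' @return Invisibly, the number of records written (records whose
#'   sequence is unavailable in the requested mode are skipped with a
#'   warning).
#' @export
write_output <- function(records, labels, comments, mode = "dna", con = "") {
  stopifnot(nrow(records) == length(labels),
            length(labels) == length(comments))
  if (identical(con, "")) con <- stdout()
  out <- character()
  written <- 0L
  for (i in seq_len(nrow(records))) {
    if (mode == "none") {
      out <- c(out, paste0(sub("^>", "", labels[i]), "\t", comments[i]))
      written <- written + 1L
      next
    }
    seq <- encode_sequence(records[i, ], mode)
    if (is.na(seq)) {
      warning("write_output: no ", mode, " sequence for '", labels[i],
              "'; record skipped", call. = FALSE)
      next
    }
    hdr <- if (startsWith(labels[i], ">")) labels[i] else paste0(">", labels[i])
    if (nzchar(comments[i])) hdr <- paste(hdr, comments[i])
    wrapped <- substring(seq, seq(1L, nchar(seq), 60L),
                         pmin(seq(60L, nchar(seq) + 59L, 60L), nchar(seq)))
    out <- c(out, hdr, wrapped)
    written <- written + 1L
  }
  writeLines(out, con)
  invisible(written)
}

#' Format pipeline output end to end
#'
#' Builds annotation dictionaries, renders label and comment templates
#' (or a preset), finalizes labels, and writes the requested output.
#'
#' @param records Representatives from [run_pipeline()].
#' @param taxonomy A `taxonomy_db` or `NULL`.
#' @param label,comment Template strings; default is the common-name
#'   preset.
#' @param preset Optional preset name overriding `label`/`comment`.
#' @param mode Sequence mode.
#' @param max_length,charset Passed to [finalize_labels()].
#' @param today Clock override for the `today` key.
#' @param con Output connection or path.
#' @return Invisibly, list with the final `labels` and `comments`.
#' @export
format_records <- function(records, taxonomy = NULL, label = NULL,
                           comment = NULL, preset = NULL, mode = "dna",
                           max_length = NULL, charset = "permissive",
                           today = Sys.Date(), con = "") {
  if (!is.null(preset)) {
    p <- label_preset(preset)
    label <- p$label; comment <- p$comment
  }
  if (is.null(label)) { p <- label_preset("common_name"); label <- p$label
    if (is.null(comment)) comment <- p$comment }
  if (is.null(comment)) comment <- ""
  n <- nrow(records)
  labels <- character(n); comments <- character(n)
  for (i in seq_len(n)) {
    d <- build_annotation(records[i, ], taxonomy, ordinal = i, today = today)
    labels[i] <- render_label(label, d)
    comments[i] <- if (nzchar(comment)) render_label(comment, d) else ""
  }
  labels <- finalize_labels(labels, max_length = max_length, charset = charset)
  write_output(records, labels, comments, mode = mode, con = con)
  invisible(list(labels = labels, comments = comments))
}
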