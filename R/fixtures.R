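#' Synthetic GenBank files and toy taxonomies
#'
#' Deterministic generators for GenBank flat files and matching taxdump
#' files, with ground truth emitted alongside so parser tests never
#' re-derive expectations from the parser itself. Sequences are random
#' with controlled composition; no evolutionary model is implied.
#'
#' @name fixtures
NULL

#' Specification for fixture generation
#'
#' @param seed RNG seed; identical seeds give byte-identical files.
#' @param n_entries Number of GenBank entries.
#' @param max_cds_per_entry CDS features per entry drawn from
#'   `1:max_cds_per_entry`.
#' @param p_partial5,p_partial3 Per-CDS probability of an incomplete
#'   5'/3' end.
#' @param p_pseudo Probability a CDS is a pseudo gene (skip-expected).
#' @param p_no_translation Probability a CDS lacks `/translation`
#'   (skip-expected).
#' @param p_ambiguous Probability the CDS carries an ambiguous base.
#' @param p_minus Probability of a minus-strand CDS.
#' @param p_spliced Probability of a multi-exon (join) location.
#' @param n_extra_taxa Random taxa added under the toy backbone.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 42L, n_entries = 25L, max_cds_per_entry = 4L,
                         p_partial5 = 0.15, p_partial3 = 0.15,
                         p_pseudo = 0.1, p_no_translation = 0.1,
                         p_ambiguous = 0.15, p_minus = 0.5, p_spliced = 0.5,
                         n_extra_taxa = 10L) {
  structure(as.list(environment()), class = "fixture_spec")
}

# Toy taxonomy backbone: a human-like lineage (9606 under genus / family /
# order), a second hominid, a rodent outgroup and a virus without a
# common name. Used by golden tests.
.toy_backbone <- function() {
  nodes <- data.frame(
    tax_id = c(1L, 9443L, 9604L, 9605L, 9606L, 9596L, 9598L,
               9989L, 10066L, 10088L, 10090L, 10239L, 12242L),
    parent = c(1L, 1L, 9443L, 9604L, 9605L, 9604L, 9596L,
               1L, 9989L, 10066L, 10088L, 1L, 10239L),
    rank = c("no rank", "order", "family", "genus", "species", "genus",
             "species", "order", "family", "genus", "species",
             "superkingdom", "species"))
  names <- data.frame(
    tax_id = c(1L, 9443L, 9604L, 9605L, 9606L, 9606L, 9596L, 9598L, 9598L,
               9989L, 10066L, 10088L, 10090L, 10090L, 10239L, 12242L),
    name = c("root", "Primates", "Hominidae", "Homo", "Homo sapiens",
             "human", "Pan", "Pan troglodytes", "chimpanzee", "Rodentia",
             "Muridae", "Mus", "Mus musculus", "house mouse", "Viruses",
             "Tobacco mosaic virus"),
    class = c("scientific name", "scientific name", "scientific name",
              "scientific name", "scientific name", "genbank common name",
              "scientific name", "scientific name", "genbank common name",
              "scientific name", "scientific name", "scientific name",
              "scientific name", "genbank common name", "scientific name",
              "scientific name"))
  list(nodes = nodes, names = names)
}

#' Write a toy taxdump
#'
#' Emits `nodes.dmp` / `names.dmp` in the NCBI dialect: the fixed
#' backbone (including Homo sapiens 9606 with common name "human") plus
#' `n_extra_taxa` random species hung under the backbone genera.
#'
#' @param spec A `fixture_spec`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, list with `nodes_path`, `names_path` and the node
#'   table used.
#' @export
make_taxdump <- function(spec = fixture_spec(), dir) {
  set.seed(spec$seed)
  bb <- .toy_backbone()
  nodes <- bb$nodes; names_df <- bb$names
  if (spec$n_extra_taxa > 0L) {
    genera <- nodes$tax_id[nodes$rank == "genus"]
    for (i in seq_len(spec$n_extra_taxa)) {
      tid <- 500000L + i
      parent <- sample(genera, 1L)
      nodes <- rbind(nodes, data.frame(tax_id = tid, parent = parent,
                                       rank = "species"))
      gname <- names_df$name[names_df$tax_id == parent &
                               names_df$class == "scientific name"]
      names_df <- rbind(names_df, data.frame(
        tax_id = tid, name = sprintf("%s synthetica%d", gname, i),
        class = "scientific name"))
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  np <- file.path(dir, "nodes.dmp")
  mp <- file.path(dir, "names.dmp")
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", nodes$tax_id, nodes$parent,
                     nodes$rank), np)
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\t%s\t|", names_df$tax_id,
                     names_df$name, names_df$class), mp)
  invisible(list(nodes_path = np, names_path = mp, nodes = nodes,
                 names = names_df))
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# A coding sequence: ATG + random codons + stop, length 3*(n_aa+1).
.rand_cds <- function(n_aa) {
  body <- .rand_dna(3L * (n_aa - 1L))
  paste0("ATG", body, sample(c("TAA", "TAG", "TGA"), 1L))
}

.translate_cds <- function(dna) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(dna), if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

#' Generate a synthetic GenBank flat file with ground truth
#'
#' Each entry holds one source feature (taxon drawn from the toy tree)
#' and 1..`max_cds_per_entry` CDS features spanning the strand, splice,
#' partial-end, pseudo and no-translation cases of the spec grid. The
#' returned ground-truth table lists, per CDS, the expected spliced
#' `dna_seq`, `aa_seq`, flags and taxon, with pseudo/no-translation CDS
#' marked `skip_expected`.
#'
#' @param spec A `fixture_spec`.
#' @param path Output file path.
#' @return Invisibly, list with `path` and `truth` (`data.table`).
#' @export
make_genbank <- function(spec = fixture_spec(), path) {
  set.seed(spec$seed + 1L)
  taxa <- .toy_backbone()
  species <- taxa$nodes$tax_id[taxa$nodes$rank == "species"]
  sci <- function(tid) taxa$names$name[taxa$names$tax_id == tid &
                                         taxa$names$class == "scientific name"]
  out <- character()
  truth <- list()
  acc_counter <- 0L
  for (e in seq_len(spec$n_entries)) {
    tid <- sample(species, 1L)
    organism <- sci(tid)
    n_cds <- sample.int(spec$max_cds_per_entry, 1L)
    cds_list <- list()
    cursor <- 50L  # leading background
    for (j in seq_len(n_cds)) {
      n_aa <- sample(20:80, 1L)
      coding <- .rand_cds(n_aa + 1L)  # n_aa+1 aa incl. Met, + stop
      is_pseudo <- stats::runif(1) < spec$p_pseudo
      no_transl <- !is_pseudo && stats::runif(1) < spec$p_no_translation
      ambiguous <- !is_pseudo && !no_transl && stats::runif(1) < spec$p_ambiguous
      if (ambiguous) {
        # ambiguity restricted to a wobble position so translation stays clean
        pos <- 3L * sample.int(nchar(coding) %/% 3L - 1L, 1L)
        substr(coding, pos, pos) <- "N"
      }
      minus <- stats::runif(1) < spec$p_minus
      n_exon <- if (stats::runif(1) < spec$p_spliced) sample(2:3, 1L) else 1L
      # split coding length into exon chunks (each >= 3 nt)
      L <- nchar(coding)
      cuts <- if (n_exon > 1L)
        sort(sample(seq(3L, L - 3L, by = 3L), n_exon - 1L)) else integer()
      chunk_len <- diff(c(0L, cuts, L))
      starts <- integer(n_exon); ends <- integer(n_exon)
      plus_content <- if (minus) reverse_complement(coding) else coding
      plus_chunks <- character(n_exon)
      off <- 0L
      lens_plus <- if (minus) rev(chunk_len) else chunk_len
      for (k in seq_len(n_exon)) {
        plus_chunks[k] <- substring(plus_content, off + 1L, off + lens_plus[k])
        off <- off + lens_plus[k]
      }
      for (k in seq_len(n_exon)) {
        cursor <- cursor + sample(5:20, 1L)  # intron / spacer
        starts[k] <- cursor + 1L
        ends[k] <- cursor + lens_plus[k]
        cursor <- ends[k]
      }
      partial5 <- stats::runif(1) < spec$p_partial5
      partial3 <- stats::runif(1) < spec$p_partial3
      left_open <- if (minus) partial3 else partial5
      right_open <- if (minus) partial5 else partial3
      segs <- sprintf("%d..%d", starts, ends)
      if (left_open) segs[1] <- paste0("<", segs[1])
      if (right_open) segs[n_exon] <- sub("\\.\\.", "..>", segs[n_exon])
      loc <- if (n_exon > 1L) sprintf("join(%s)", paste(segs, collapse = ","))
             else segs[1]
      if (minus) loc <- sprintf("complement(%s)", loc)
      acc_counter <- acc_counter + 1L
      refseq <- stats::runif(1) < 0.3
      acc <- if (refseq) sprintf("XP_%06d.1", acc_counter)
             else sprintf("SYN%05d.1", acc_counter)
      gi <- 900000L + acc_counter
      aa <- .translate_cds(coding)
      cds_list[[j]] <- list(
        loc = loc, acc = acc, gi = gi, pseudo = is_pseudo,
        no_transl = no_transl, aa = aa, gene = sprintf("gene%d", acc_counter),
        chunks = stats::setNames(plus_chunks, NULL), starts = starts,
        ends = ends)
      truth[[length(truth) + 1L]] <- data.table::data.table(
        protein_accession = acc, gi = as.character(gi), taxon_id = tid,
        organism = organism, location = loc,
        strand = if (minus) -1L else 1L,
        dna_seq = coding, aa_seq = if (no_transl || is_pseudo) NA_character_
                                   else aa,
        partial5 = partial5, partial3 = partial3,
        cds_length = nchar(coding),
        skip_expected = is_pseudo || no_transl,
        skip_reason = if (is_pseudo) "pseudo"
                      else if (no_transl) "no_translation" else "")
    }
    # assemble the plus-strand origin: background with CDS chunks embedded
    total_len <- cursor + sample(20:60, 1L)
    origin <- strsplit(.rand_dna(total_len), "")[[1]]
    for (cds in cds_list)
      for (k in seq_along(cds$starts))
        origin[cds$starts[k]:cds$ends[k]] <-
          strsplit(cds$chunks[k], "")[[1]]
    origin <- paste(origin, collapse = "")
    src_acc <- sprintf("FX%06d", e)
    out <- c(out, .format_entry(src_acc, origin, organism, tid, cds_list))
    for (idx in (length(truth) - n_cds + 1L):length(truth))
      truth[[idx]]$source_accession <- paste0(src_acc, ".1")
  }
  writeLines(out, path)
  tr <- data.table::rbindlist(truth, use.names = TRUE, fill = TRUE)
  invisible(list(path = path, truth = tr))
}

.wrap_qualifier <- function(text, width = 58L) {
  substring(text, seq(1L, nchar(text), width),
            pmin(seq(width, nchar(text) + width - 1L, width), nchar(text)))
}

.format_entry <- function(src_acc, origin, organism, taxon, cds_list) {
  q <- function(s) paste0(strrep(" ", 21L), s)
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     linear   SYN 10-MAY-2013",
            src_acc, nchar(origin)),
    sprintf("DEFINITION  synthetic fixture entry %s.", src_acc),
    sprintf("ACCESSION   %s", src_acc),
    sprintf("VERSION     %s.1", src_acc),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(origin)),
    q(sprintf("/organism=\"%s\"", organism)),
    q("/mol_type=\"genomic DNA\""),
    q(sprintf("/db_xref=\"taxon:%d\"", taxon)))
  for (cds in cds_list) {
    lines <- c(lines, sprintf("     CDS             %s", cds$loc),
               q(sprintf("/gene=\"%s\"", cds$gene)))
    if (cds$pseudo) {
      lines <- c(lines, q("/pseudo"))
      next
    }
    lines <- c(lines,
               q("/codon_start=1"), q("/transl_table=1"),
               q(sprintf("/product=\"%s product\"", cds$gene)),
               q(sprintf("/protein_id=\"%s\"", cds$acc)),
               q(sprintf("/db_xref=\"GI:%d\"", cds$gi)))
    if (!cds$no_transl) {
      tl <- .wrap_qualifier(sprintf("/translation=\"%s\"", cds$aa))
      lines <- c(lines, vapply(tl, q, ""))
    }
  }
  lines <- c(lines, "ORIGIN      ")
  s <- tolower(origin)
  for (start in seq(1L, nchar(s), 60L)) {
    chunk <- substring(s, start, min(start + 59L, nchar(s)))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", start, paste(groups, collapse = " ")))
  }
  c(lines, "//")
}

#' Fabricate a CDS record directly
#'
#' Convenience constructor for tests and examples: builds a fully
#' populated record row from a DNA sequence (translated internally when
#' `aa_seq` is not given), with hashes, GC content and flags computed.
#'
#' @param protein_accession Accession string.
#' @param dna_seq CDS nucleotide sequence (or `NA` for protein-only).
#' @param aa_seq Protein sequence; derived from `dna_seq` when `NA`.
#' @param taxon_id,organism,gene,gi,source_accession,source_length,
#'   partial5,partial3,entry_date Optional annotation fields.
#' @return One-row CDS `data.table`.
#' @export
make_record <- function(protein_accession, dna_seq = NA_character_,
                        aa_seq = NA_character_, taxon_id = NA_integer_,
                        organism = NA_character_, gene = NA_character_,
                        gi = NA_character_, source_accession = NA_character_,
                        source_length = NA_integer_, partial5 = FALSE,
                        partial3 = FALSE, entry_date = NA_character_) {
  if (is.na(aa_seq) && !is.na(dna_seq)) aa_seq <- .translate_cds(dna_seq)
  r <- empty_cds_table()[1, ]
  r$protein_accession <- protein_accession
  r$accession_stem <- accession_stem(protein_accession)
  r$gi <- as.character(gi)
  r$source_accession <- source_accession
  r$taxon_id <- as.integer(taxon_id)
  r$organism <- organism
  r$gene <- gene
  r$codon_start <- 1L
  r$transl_table <- 1L
  r$strand <- 1L
  r$dna_seq <- if (is.na(dna_seq)) NA_character_ else toupper(dna_seq)
  r$aa_seq <- if (is.na(aa_seq)) NA_character_ else toupper(aa_seq)
  r$dna_md5 <- if (is.na(dna_seq)) NA_character_ else sequence_md5(dna_seq, "dna")
  r$prot_md5 <- if (is.na(aa_seq)) NA_character_ else sequence_md5(aa_seq, "protein")
  r$partial5 <- partial5
  r$partial3 <- partial3
  r$is_refseq <- is_refseq(protein_accession)
  r$cds_length <- if (is.na(dna_seq)) NA_integer_ else nchar(dna_seq)
  r$source_length <- if (is.na(source_length) && !is.na(dna_seq))
    nchar(dna_seq) else as.integer(source_length)
  r$pcGC <- if (is.na(dna_seq)) NA_real_ else percent_gc(dna_seq)
  r$entry_date <- entry_date
  r$passthrough <- FALSE
  r
}
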