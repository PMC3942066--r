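#' Indexed CDS store
#'
#' An in-process store of CDS records with the index set needed for exact
#' retrieval: protein accession (versioned and unversioned stem), GI,
#' protein/DNA sequence MD5, and the compound (MD5, taxon) keys.
#' Re-inserting a record whose accession stem matches an existing record
#' replaces it, so only the latest version of an entry is retained.
#' The store holds a [data.table::data.table] behind the scenes and can be
#' persisted to a single file.
#'
#' @name cds-store
NULL

#' Create an empty CDS store
#'
#' @param taxonomy Optional `taxonomy_db` to bundle with the store (used
#'   for counters and downstream taxonomy-aware queries).
#' @return A `cds_store` object.
#' @export
cds_store <- function(taxonomy = NULL) {
  st <- new.env(parent = emptyenv())
  st$records <- empty_cds_table()
  st$taxonomy <- taxonomy
  class(st) <- "cds_store"
  st
}

#' Insert records into the store
#'
#' Latest-wins on the accession stem: a new version of an accession
#' replaces the stored one. Per-taxon CDS counters of the bundled
#' taxonomy are incremented once per newly inserted record.
#'
#' @param store A `cds_store`.
#' @param records One-or-more-row CDS `data.table` (as produced by
#'   [parse_genbank()]).
#' @return The store, invisibly.
#' @export
store_put <- function(store, records) {
  stopifnot(inherits(store, "cds_store"))
  if (nrow(records) == 0L) return(invisible(store))
  records <- data.table::as.data.table(records)
  # within the batch, keep the last occurrence of each stem
  records <- records[!duplicated(records$accession_stem, fromLast = TRUE), ]
  old <- store$records
  keep <- !(old$accession_stem %in% records$accession_stem)
  store$records <- data.table::rbindlist(list(old[keep, ], records),
                                         use.names = TRUE, fill = TRUE)
  if (!is.null(store$taxonomy)) tally_cds(store$taxonomy, records$taxon_id)
  invisible(store)
}

#' Number of stored records
#' @param store A `cds_store`.
#' @return Integer count.
#' @export
store_size <- function(store) nrow(store$records)

#' Retrieve a record by identifier
#'
#' A versioned accession must match exactly; an unversioned accession
#' matches the stored (latest) version; an all-digit token is tried as a
#' GI first, then as an accession.
#'
#' @param store A `cds_store`.
#' @param identifier Accession (with or without version) or GI string.
#' @return One-row `data.table` or `NULL`.
#' @export
store_get_by_id <- function(store, identifier) {
  r <- store$records
  id <- trimws(identifier)
  if (!nzchar(id)) return(NULL)
  if (grepl("^[0-9]+$", id)) {
    hit <- which(!is.na(r$gi) & r$gi == id)
    if (length(hit)) return(r[hit[1], ])
  }
  if (grepl("\\.[0-9]+$", id)) {
    hit <- which(r$protein_accession == id)
  } else {
    hit <- which(r$accession_stem == id)
  }
  if (length(hit)) r[hit[1], ] else NULL
}

#' Retrieve records by sequence hash
#'
#' @param store A `cds_store`.
#' @param md5 32-hex digest of the (uppercased) sequence.
#' @param kind `"protein"` or `"dna"`: which hash index to query.
#' @param taxon_id Optional taxon restriction (the compound index).
#' @return `data.table` of matching records (possibly zero rows).
#' @export
store_get_by_hash <- function(store, md5, kind = c("protein", "dna"),
                              taxon_id = NULL) {
  kind <- match.arg(kind)
  if (!grepl("^[0-9a-f]{32}$", md5))
    stop("store_get_by_hash: malformed md5 '", md5, "'")
  r <- store$records
  col <- if (kind == "protein") r$prot_md5 else r$dna_md5
  sel <- !is.na(col) & col == md5
  if (!is.null(taxon_id) && !is.na(taxon_id))
    sel <- sel & !is.na(r$taxon_id) & r$taxon_id == as.integer(taxon_id)
  r[sel, ]
}

#' Count of store records sharing a protein hash
#'
#' Used as the "number of times the protein sequence is represented in
#' GenBank" criterion of representative selection; computed at query
#' time over the whole store.
#'
#' @param store A `cds_store`.
#' @param prot_md5 Character vector of protein hashes (`NA` gives 0).
#' @return Integer vector of counts.
#' @export
store_representation_count <- function(store, prot_md5) {
  tab <- table(store$records$prot_md5)
  out <- as.integer(tab[prot_md5])
  out[is.na(out)] <- 0L
  out
}

#' Persist / restore a store
#'
#' One file per build; records and the bundled taxonomy (tree plus CDS
#' counters) travel together.
#'
#' @param store A `cds_store`.
#' @param path File path.
#' @return `store_load` returns a `cds_store`; `store_save` the path,
#'   invisibly.
#' @export
store_save <- function(store, path) {
  tax <- store$taxonomy
  obj <- list(records = as.data.frame(store$records),
              tax_nodes = if (is.null(tax)) NULL else as.data.frame(tax$nodes),
              tax_root = if (is.null(tax)) NULL else tax$root_id)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname store_save
#' @export
store_load <- function(path) {
  obj <- readRDS(path)
  tax <- NULL
  if (!is.null(obj$tax_nodes)) {
    tax <- new.env(parent = emptyenv())
    tax$nodes <- data.table::as.data.table(obj$tax_nodes)
    data.table::setkey(tax$nodes, tax_id)
    tax$root_id <- obj$tax_root
    class(tax) <- "taxonomy_db"
  }
  st <- cds_store(taxonomy = tax)
  rec <- data.table::as.data.table(obj$records)
  data.table::setattr(rec, "class", c("cds_table", class(rec)))
  st$records <- rec
  st
}

#' Build a store from GenBank files and a taxdump
#'
#' Convenience composition of [load_taxdump()], [parse_genbank()] and
#' [store_put()]; logs a per-file ingest report.
#'
#' @param genbank_files Character vector of GenBank flat-file paths.
#' @param taxdump_dir Directory containing `nodes.dmp` and `names.dmp`.
#' @param verbose Print per-file ingest reports.
#' @return A populated `cds_store`.
#' @export
build_store <- function(genbank_files, taxdump_dir, verbose = TRUE) {
  tax <- load_taxdump(file.path(taxdump_dir, "nodes.dmp"),
                      file.path(taxdump_dir, "names.dmp"))
  st <- cds_store(taxonomy = tax)
  for (f in genbank_files) {
    recs <- parse_genbank(f)
    rep <- attr(recs, "report")
    if (verbose)
      message(sprintf(
        "%s: %d entries, %d CDS kept, %d pseudo skipped, %d without translation",
        basename(f), rep["entries"], rep["cds_kept"],
        rep["skipped_pseudo"], rep["skipped_no_translation"]))
    store_put(st, recs)
  }
  st
}

#' @export
print.cds_store <- function(x, ...) {
  cat(sprintf("<cds_store: %d records%s>\n", nrow(x$records),
              if (is.null(x$taxonomy)) "" else
                sprintf(", taxonomy of %d taxa", nrow(x$taxonomy$nodes))))
  invisible(x)
}
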