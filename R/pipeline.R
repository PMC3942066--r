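#' Selection pipeline: expansion, clustering, quality, representatives
#'
#' The engine that turns resolved records into a curated set: optional
#' expansion to identical proteins (all taxa) or synonymous CDS (same
#' taxon), redundancy clustering by accession / sequence hash / taxonomic
#' rank, per-member quality flags, and selection of the optimal cluster
#' representative by the ordered criteria: species importance, RefSeq
#' membership, protein representation count, CDS length, source length,
#' input order.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param expansion `"none"`, `"full"` (identical proteins in all taxa)
#'   or `"cds_within_taxon"` (synonymous CDS, same taxon).
#' @param redundancy_key `"accession"`, `"protein_seq"`, `"dna_seq"`,
#'   `"protein_seq_by_taxon"`, `"dna_seq_by_taxon"`, or `"tax_rank"`
#'   (with `rank`).
#' @param rank Rank label for `redundancy_key = "tax_rank"`.
#' @param n_incomplete,c_incomplete,dna_ambiguous,aa_ambiguous Quality
#'   toggles; default all on.
#' @param length_range Optional `c(min, max)` in residues of the output
#'   sequence kind.
#' @param empty_cluster_policy `"best_effort"` (member with the most
#'   non-ambiguous residues represents an all-flagged cluster) or
#'   `"drop"` (leave such clusters unrepresented).
#' @param seq_mode Output sequence representation: `"dna"` (default),
#'   `"aa"`, `"wobble_ry"`, `"ry"`, or `"none"`. Determines the sequence
#'   kind on which length and "most non-ambiguous residues" are
#'   evaluated.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expansion = c("none", "full", "cds_within_taxon"),
                            redundancy_key = c("accession", "protein_seq",
                                               "dna_seq",
                                               "protein_seq_by_taxon",
                                               "dna_seq_by_taxon", "tax_rank"),
                            rank = NULL,
                            n_incomplete = TRUE, c_incomplete = TRUE,
                            dna_ambiguous = TRUE, aa_ambiguous = TRUE,
                            length_range = NULL,
                            empty_cluster_policy = c("best_effort", "drop"),
                            seq_mode = c("dna", "aa", "wobble_ry", "ry",
                                         "none")) {
  expansion <- match.arg(expansion)
  redundancy_key <- match.arg(redundancy_key)
  if (redundancy_key == "tax_rank" && is.null(rank))
    stop("pipeline_config: redundancy_key 'tax_rank' requires a rank")
  structure(list(expansion = expansion, redundancy_key = redundancy_key,
                 rank = rank,
                 toggles = c(n_incomplete = n_incomplete,
                             c_incomplete = c_incomplete,
                             dna_ambiguous = dna_ambiguous,
                             aa_ambiguous = aa_ambiguous),
                 length_range = length_range,
                 empty_cluster_policy = match.arg(empty_cluster_policy),
                 seq_mode = match.arg(seq_mode)),
            class = "pipeline_config")
}

# sequence kind the output is judged on: wobble/ry/none act on DNA;
# "none" (property files) defaults to the protein sequence.
.output_kind <- function(config) {
  switch(config$seq_mode, aa = "protein", none = "protein", "dna")
}

#' Expand records to identical proteins / synonymous CDS
#'
#' `full`: for each input record append every store record sharing its
#' protein hash, across all taxa. `cds_within_taxon`: only records
#' sharing (protein hash, taxon). Duplicate accessions arising from
#' overlapping expansions are kept once, at first appearance; the
#' originating record's `input_ordinal` is inherited.
#'
#' @param records Resolved CDS `data.table` with `input_ordinal`.
#' @param mode Expansion mode string.
#' @param store A `cds_store`.
#' @return Ordered expanded `data.table`.
#' @export
expand_records <- function(records, mode, store) {
  if (mode == "none" || nrow(records) == 0L) return(records)
  blocks <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (isTRUE(r$passthrough) || is.na(r$prot_md5)) { blocks[[i]] <- r; next }
    hits <- store_get_by_hash(store, r$prot_md5, "protein",
                              taxon_id = if (mode == "cds_within_taxon")
                                r$taxon_id else NULL)
    if (nrow(hits) == 0L) { blocks[[i]] <- r; next }
    hits <- data.table::copy(hits)
    hits$input_ordinal <- r$input_ordinal
    hits$orig_label <- r$orig_label
    # the seed record leads its own expansion block
    self <- which(hits$protein_accession == r$protein_accession)
    if (length(self)) hits <- hits[c(self[1], setdiff(seq_len(nrow(hits)), self[1])), ]
    blocks[[i]] <- hits
  }
  out <- data.table::rbindlist(blocks, use.names = TRUE, fill = TRUE)
  out[!duplicated(out$protein_accession), ]
}

#' Per-record quality flags
#'
#' Flags: incomplete N-terminus (5' partial), incomplete C-terminus
#' (3' partial), ambiguous CDS residues, ambiguous amino acids, length
#' outside the user range. A record passes when no *enabled* flag is
#' set. Passthrough records have unknown completeness (flags false);
#' ambiguity is computed from the provided sequence. Length and the
#' ambiguity criterion of the length check use the output sequence kind.
#'
#' @param records CDS `data.table`.
#' @param config A `pipeline_config`.
#' @return `data.table` of logical columns `n_incomplete`,
#'   `c_incomplete`, `dna_ambiguous`, `aa_ambiguous`,
#'   `length_out_of_range`, `passes`.
#' @export
quality_flags <- function(records, config) {
  n <- nrow(records)
  fl <- data.table::data.table(
    n_incomplete = !is.na(records$partial5) & records$partial5,
    c_incomplete = !is.na(records$partial3) & records$partial3,
    dna_ambiguous = !is.na(records$dna_seq) & dna_is_ambiguous(records$dna_seq),
    aa_ambiguous = !is.na(records$aa_seq) & aa_is_ambiguous(records$aa_seq))
  kind <- .output_kind(config)
  out_seq <- if (kind == "dna") records$dna_seq else records$aa_seq
  loor <- rep(FALSE, n)
  if (!is.null(config$length_range)) {
    len <- ifelse(is.na(out_seq), NA_integer_, nchar(out_seq))
    loor <- is.na(len) | len < config$length_range[1] |
      len > config$length_range[2]
  }
  fl$length_out_of_range <- loor
  enabled <- cbind(
    if (config$toggles["n_incomplete"]) fl$n_incomplete else FALSE,
    if (config$toggles["c_incomplete"]) fl$c_incomplete else FALSE,
    if (config$toggles["dna_ambiguous"]) fl$dna_ambiguous else FALSE,
    if (config$toggles["aa_ambiguous"]) fl$aa_ambiguous else FALSE,
    if (!is.null(config$length_range)) fl$length_out_of_range else FALSE)
  fl$passes <- !apply(enabled, 1L, any)
  fl
}

#' Cluster records by a redundancy key
#'
#' Keys: accession (each accession once, the default), protein/DNA
#' sequence hash (NR-style merging), the same compounded with taxon
#' (duplicate sequences in different taxa are retained), or the taxon of
#' the ancestor at a requested rank (one sequence per clade). When a
#' record's lineage lacks the requested rank it clusters alone under its
#' own taxon. Clusters are ordered by first member appearance.
#'
#' @param records Ordered CDS `data.table`.
#' @param config A `pipeline_config` (or a redundancy key string).
#' @param taxonomy A `taxonomy_db` (needed for `tax_rank`).
#' @return List of clusters: `key`, `members` (`data.table` with row
#'   column `member_ordinal` preserved from input order).
#' @export
cluster_records <- function(records, config, taxonomy = NULL) {
  if (is.character(config)) config <- pipeline_config(redundancy_key = config)
  n <- nrow(records)
  if (n == 0L) return(list())
  key <- switch(
    config$redundancy_key,
    accession = ifelse(is.na(records$protein_accession),
                       paste0("@pt", seq_len(n)), records$protein_accession),
    protein_seq = ifelse(is.na(records$prot_md5),
                         paste0("@pt", seq_len(n)), records$prot_md5),
    dna_seq = ifelse(is.na(records$dna_md5),
                     paste0("@pt", seq_len(n)), records$dna_md5),
    protein_seq_by_taxon = ifelse(
      is.na(records$prot_md5), paste0("@pt", seq_len(n)),
      paste(records$prot_md5, records$taxon_id, sep = "|")),
    dna_seq_by_taxon = ifelse(
      is.na(records$dna_md5), paste0("@pt", seq_len(n)),
      paste(records$dna_md5, records$taxon_id, sep = "|")),
    tax_rank = .rank_key(records$taxon_id, config$rank, taxonomy))
  idx <- split(seq_len(n), factor(key, levels = unique(key)))
  lapply(names(idx), function(k) {
    m <- records[idx[[k]], ]
    m$member_ordinal <- idx[[k]]
    list(key = k, members = m)
  })
}

.rank_key <- function(taxon_id, rank, taxonomy) {
  if (is.null(taxonomy)) stop("cluster_records: tax_rank needs a taxonomy")
  vapply(seq_along(taxon_id), function(i) {
    tid <- taxon_id[i]
    if (is.na(tid)) return(paste0("@na", i))
    anc <- if (tid %in% taxonomy$nodes$tax_id)
      ancestor_at_rank(taxonomy, tid, rank) else NULL
    if (is.null(anc)) as.character(tid) else as.character(anc$tax_id)
  }, "")
}

#' Select the optimal cluster representative
#'
#' Members passing quality control are candidates; a single candidate
#' wins outright. Several candidates are ordered lexicographically by
#' (1) species importance (annotated-CDS count of the taxon), (2) RefSeq
#' membership, (3) store-wide protein representation count, (4) CDS
#' length, (5) source entry length — all maximized — then (6) minimal
#' input order. When no member passes, `best_effort` picks the member
#' with the most non-ambiguous residues in the output sequence kind
#' (ties by input order) and `drop` leaves the cluster unrepresented.
#'
#' @param cluster A cluster from [cluster_records()].
#' @param store A `cds_store` (for representation counts).
#' @param taxonomy A `taxonomy_db` (for importance).
#' @param config A `pipeline_config`.
#' @param flags Optional precomputed [quality_flags()] rows for the
#'   members.
#' @return One-row `data.table`, or `NULL` for a dropped cluster.
#' @export
select_representative <- function(cluster, store, taxonomy, config,
                                  flags = NULL) {
  m <- cluster$members
  if (is.null(flags)) flags <- quality_flags(m, config)
  cand <- which(flags$passes)
  if (length(cand) == 0L) {
    if (config$empty_cluster_policy == "drop") return(NULL)
    score <- n_unambiguous(
      if (.output_kind(config) == "dna") m$dna_seq else m$aa_seq,
      .output_kind(config))
    ord <- order(-score, m$input_ordinal, m$member_ordinal)
    return(m[ord[1], ])
  }
  if (length(cand) == 1L) return(m[cand, ])
  mc <- m[cand, ]
  imp <- if (is.null(taxonomy)) rep(0L, nrow(mc)) else
    species_importance(taxonomy, mc$taxon_id)
  refseq <- !is.na(mc$is_refseq) & mc$is_refseq
  repcnt <- store_representation_count(store, mc$prot_md5)
  cdsl <- ifelse(is.na(mc$cds_length), 0L, mc$cds_length)
  srcl <- ifelse(is.na(mc$source_length), 0L, mc$source_length)
  ord <- order(-imp, -refseq, -repcnt, -cdsl, -srcl,
               mc$input_ordinal, mc$member_ordinal)
  mc[ord[1], ]
}

#' Run the full selection pipeline
#'
#' resolve -> expand -> cluster -> flag -> select. Returns the ordered
#' representatives and a stage-by-stage report.
#'
#' @param selection Selection text (see [parse_selection()]) or a list of
#'   selector items.
#' @param config A `pipeline_config`.
#' @param store A `cds_store`.
#' @param taxonomy A `taxonomy_db` (defaults to the store's).
#' @return List with `records` (representatives, ordered by first cluster
#'   appearance) and `report`.
#' @export
run_pipeline <- function(selection, config, store,
                         taxonomy = store$taxonomy) {
  items <- if (is.character(selection)) parse_selection(selection) else selection
  res <- resolve_selection(items, store, taxonomy)
  expanded <- expand_records(res$records, config$expansion, store)
  clusters <- cluster_records(expanded, config, taxonomy)
  reps <- list()
  dropped <- 0L
  for (cl in clusters) {
    r <- select_representative(cl, store, taxonomy, config)
    if (is.null(r)) dropped <- dropped + 1L
    else reps[[length(reps) + 1L]] <- r
  }
  records <- if (length(reps))
    data.table::rbindlist(reps, use.names = TRUE, fill = TRUE)
  else cbind(empty_cds_table(),
             data.table::data.table(input_ordinal = integer(),
                                    member_ordinal = integer()))
  report <- c(res$report,
              list(expanded = nrow(expanded), clusters = length(clusters),
                   clusters_dropped = dropped, output_records = nrow(records)))
  list(records = records, report = report)
}
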