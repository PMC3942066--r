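#' NCBI taxonomy tree
#'
#' Loads `nodes.dmp` / `names.dmp` (fields separated by `"\t|\t"`, records
#' terminated by `"\t|"`) into an indexed tree supporting lineage
#' traversal, rank lookup and per-taxon CDS counters. The counter for a
#' taxon, incremented once per annotated CDS during ingest, serves as a
#' proxy for the relative scientific interest of the species.
#'
#' @name taxonomy
NULL

#' Load an NCBI taxdump
#'
#' Scientific names come from name class `"scientific name"`; common names
#' from `"genbank common name"`, falling back to `"common name"`. Other
#' classes (synonyms etc.) never override these.
#'
#' @param nodes_path Path to `nodes.dmp` (tax_id | parent | rank | ...).
#' @param names_path Path to `names.dmp` (tax_id | name | unique | class).
#' @return A `taxonomy_db` object (environment with a node table).
#' @export
load_taxdump <- function(nodes_path, names_path) {
  nodes <- .read_dmp(nodes_path)
  if (ncol(nodes) < 3L) stop("load_taxdump: nodes.dmp needs >= 3 fields")
  nd <- data.table::data.table(
    tax_id = as.integer(nodes[[1]]),
    parent_id = as.integer(nodes[[2]]),
    rank = as.character(nodes[[3]]))
  if (anyDuplicated(nd$tax_id))
    stop("load_taxdump: duplicate tax_id ",
         nd$tax_id[duplicated(nd$tax_id)][1])
  missing_parent <- setdiff(nd$parent_id, nd$tax_id)
  if (length(missing_parent))
    stop("load_taxdump: parent taxon ", missing_parent[1], " not present")

  nm <- .read_dmp(names_path)
  if (ncol(nm) < 4L) stop("load_taxdump: names.dmp needs 4 fields")
  nmdt <- data.table::data.table(tax_id = as.integer(nm[[1]]),
                                 name = as.character(nm[[2]]),
                                 class = as.character(nm[[4]]))
  sci <- nmdt[nmdt$class == "scientific name", ]
  com <- nmdt[nmdt$class == "genbank common name", ]
  com2 <- nmdt[nmdt$class == "common name", ]
  nd$scientific_name <- sci$name[match(nd$tax_id, sci$tax_id)]
  nd$common_name <- com$name[match(nd$tax_id, com$tax_id)]
  fb <- is.na(nd$common_name)
  nd$common_name[fb] <- com2$name[match(nd$tax_id[fb], com2$tax_id)]
  nd$cds_count <- 0L
  data.table::setkey(nd, tax_id)

  db <- new.env(parent = emptyenv())
  db$nodes <- nd
  db$root_id <- nd$tax_id[nd$tax_id == nd$parent_id][1]
  if (is.na(db$root_id)) stop("load_taxdump: no root node (self-parent)")
  .check_acyclic(db)
  class(db) <- "taxonomy_db"
  db
}

.read_dmp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\t\\|$", "", lines)
  parts <- strsplit(lines, "\t|\t", fixed = TRUE)
  n <- max(lengths(parts))
  data.table::setDT(lapply(seq_len(n), function(i)
    vapply(parts, function(p) if (length(p) >= i) p[i] else NA_character_, "")))
}

.check_acyclic <- function(db) {
  nd <- db$nodes
  depth <- rep(NA_integer_, nrow(nd))
  names(depth) <- as.character(nd$tax_id)
  for (id in nd$tax_id) {
    seen <- integer(0)
    cur <- id
    while (cur != db$root_id) {
      if (cur %in% seen) stop("load_taxdump: cycle at taxon ", id)
      if (length(seen) > nrow(nd)) stop("load_taxdump: cycle at taxon ", id)
      seen <- c(seen, cur)
      cur <- nd$parent_id[match(cur, nd$tax_id)]
    }
  }
  invisible(TRUE)
}

.tax_node <- function(db, tax_id) {
  i <- match(tax_id, db$nodes$tax_id)
  if (is.na(i)) stop("taxonomy: unknown tax_id ", tax_id)
  db$nodes[i, ]
}

#' Taxonomic lineage, root first
#'
#' @param db A `taxonomy_db`.
#' @param tax_id Integer taxon identifier.
#' @return `data.table` of lineage nodes, root first, query node last.
#' @export
lineage <- function(db, tax_id) {
  .tax_node(db, tax_id)  # existence check
  path <- integer(0)
  cur <- as.integer(tax_id)
  repeat {
    path <- c(cur, path)
    if (cur == db$root_id) break
    cur <- db$nodes$parent_id[match(cur, db$nodes$tax_id)]
  }
  db$nodes[match(path, db$nodes$tax_id), ]
}

#' Ancestor of a taxon at a given rank
#'
#' @param db A `taxonomy_db`.
#' @param tax_id Integer taxon identifier.
#' @param rank Rank label (`"species"`, `"genus"`, `"family"`, ...).
#' @return One-row `data.table`, or `NULL` when the lineage has no node of
#'   that rank.
#' @export
ancestor_at_rank <- function(db, tax_id, rank) {
  lin <- lineage(db, tax_id)
  hit <- which(lin$rank == rank)
  if (length(hit) == 0L) return(NULL)
  lin[hit[1], ]
}

#' CDS counter of a taxon (species-importance proxy)
#'
#' @param db A `taxonomy_db`.
#' @param tax_id Integer taxon id (vectorized). Unknown/`NA` ids give 0
#'   so that records without taxonomy sort last in importance.
#' @return Integer vector of leaf CDS counts.
#' @export
species_importance <- function(db, tax_id) {
  cnt <- db$nodes$cds_count[match(as.integer(tax_id), db$nodes$tax_id)]
  cnt[is.na(cnt)] <- 0L
  cnt
}

#' Increment per-taxon CDS counters
#'
#' Called once per ingested CDS; counts attach to the annotated (leaf)
#' taxon only. Unknown taxa are ignored.
#'
#' @param db A `taxonomy_db`.
#' @param tax_ids Integer vector (one element per CDS; repeats allowed).
#' @return The db, invisibly.
#' @export
tally_cds <- function(db, tax_ids) {
  tab <- table(tax_ids[!is.na(tax_ids)])
  i <- match(as.integer(names(tab)), db$nodes$tax_id)
  ok <- !is.na(i)
  db$nodes$cds_count[i[ok]] <- db$nodes$cds_count[i[ok]] + as.integer(tab[ok])
  invisible(db)
}

#' Aggregated CDS count over a subtree
#'
#' Leaf counters summed over a taxon and all its descendants; a derived
#' query for rank-level reporting (importance comparisons use leaf
#' counts).
#'
#' @param db A `taxonomy_db`.
#' @param tax_id Integer taxon id.
#' @return Integer total.
#' @export
subtree_cds_count <- function(db, tax_id) {
  .tax_node(db, tax_id)
  nd <- db$nodes
  acc <- 0L
  frontier <- as.integer(tax_id)
  while (length(frontier)) {
    acc <- acc + sum(nd$cds_count[nd$tax_id %in% frontier])
    frontier <- nd$tax_id[nd$parent_id %in% frontier & nd$tax_id != db$root_id]
  }
  acc
}

#' Find a taxon by name (exact, case-insensitive)
#'
#' Matches scientific name first, then common name. Used to resolve the
#' `[Species name]` bracket hint on FASTA title lines.
#'
#' @param db A `taxonomy_db`.
#' @param name Name string.
#' @return Integer tax_id or `NA` when no exact match exists.
#' @export
taxon_by_name <- function(db, name) {
  if (is.null(name) || is.na(name) || !nzchar(name)) return(NA_integer_)
  lw <- tolower(trimws(name))
  i <- which(tolower(db$nodes$scientific_name) == lw)
  if (length(i) == 0L) i <- which(tolower(db$nodes$common_name) == lw)
  if (length(i) == 0L) NA_integer_ else db$nodes$tax_id[i[1]]
}

#' @export
print.taxonomy_db <- function(x, ...) {
  cat(sprintf("<taxonomy_db: %d taxa, root=%d, %d CDS tallied>\n",
              nrow(x$nodes), x$root_id, sum(x$nodes$cds_count)))
  invisible(x)
}
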