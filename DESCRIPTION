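Package: cdskit
Title: Taxonomy-Aware Extraction, Selection and Relabeling of
    Protein-Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds an indexed local store of protein-coding sequences
    (CDS) from GenBank flat files and NCBI taxonomy dump files, then
    selects, expands, de-duplicates, quality-filters, renames and
    formats protein or DNA sequence sets with full taxonomy awareness.
    Sequence sets are resolved from identifier lists or FASTA input
    with MD5 hash fallback, expanded to synonymous CDS or identical
    proteins in other species, clustered by accession, sequence
    identity or taxonomic rank, and represented by the best-quality
    member of each cluster. A printf-style template engine renders
    sequence labels and labeled property files for phylogenetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    digest,
    Biostrings,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
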