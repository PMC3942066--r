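---
title: "cdskit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cdskit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdskit)
```

This vignette explains what each stage of the `cdskit` pipeline computes,
the assumptions behind it, the parameters that matter, and the design
choices made where the behavior was genuinely open. It states no
empirical result that the package's tests do not themselves compute.

## 1. Ingest: from GenBank flat files to CDS records

A GenBank nucleotide entry describes one (usually longer) sequence
containing zero or more CDS features. `parse_genbank()` emits one record
per CDS feature carrying a `/translation` qualifier; pseudo genes
(`/pseudo`) and translation-less CDS are skipped and counted in the
per-file ingest report. The `/translation` string is taken as
authoritative — the package never re-translates DNA, so annotation
errors in GenBank surface as data, not as silent corrections.

**Feature locations.** The location grammar supported is the subset CDS
annotation actually uses: `a..b`, single bases, `join(...)` and a single
outer `complement(...)`, with `<`/`>` open-end markers. `order()`,
`bond()` and `complement()` nested inside `join()` (trans-spliced or
mixed-strand features) are rejected with the offending text;
mixed-strand CDS are rare, biologically exotic, and ambiguous to splice.
The spliced CDS sequence is the concatenation of the plus-strand slices,
reverse-complemented for minus-strand locations so it always reads 5′→3′
on the coding strand.

**Partial-end flags.** The `<` marker sits on the smallest plus-strand
coordinate and `>` on the largest. On the plus strand these are the 5′
and 3′ ends; on the minus strand the mapping must be swapped — a
`complement(<10..>30)` CDS has its 5′ end at position 30. The flags are
stored strand-corrected (`partial5`, `partial3`), which is the only
biologically coherent reading and the basis of the N-/C-terminus quality
flags downstream.

**Derived annotation.** Per record: MD5 hashes of the uppercased DNA and
protein sequences (whitespace stripped; stop `*` stripped from proteins
before hashing so translations with and without the annotated stop
compare equal), percent GC (G+C+S over length — `S` is the IUPAC
strong code and provably G or C; other ambiguity codes count only in the
denominator), CDS length, source entry length, entry date, and RefSeq
membership inferred from the accession's underscore shape (`NP_`,
`XP_`, `WP_`, ...), the stable lexical signature of that collection.

**Ambiguity definitions.** DNA is ambiguous when any character falls
outside `A/C/G/T`; protein when any character falls outside the 20
standard amino acids (stop `*` ignored). These are the simplest testable
rules and deliberately strict: `U`, `N`, `X`, `B`, `Z` all count as
ambiguous.

`/codon_start` offsets greater than 1 do not trim the stored DNA: the
record keeps the literal located span with `codon_start` as annotation,
preserving the GenBank record faithfully. Coordinates are 1-based
inclusive throughout.

## 2. Taxonomy

`load_taxdump()` reads the `nodes.dmp`/`names.dmp` dialect (fields
separated by `"\t|\t"`). Scientific names come from name class
`"scientific name"`; common names from `"genbank common name"` with
`"common name"` as fallback; synonyms never override either. Loading
validates the tree: duplicate ids and dangling parents are errors, the
root is the unique self-parent, and every lineage is checked finite.

Each annotated CDS increments a counter on its *annotated* taxon — the
leaf, typically a species or strain. This count is the species-importance
proxy used in representative selection: heavily sequenced taxa are, on
average, the well-studied ones a reader will recognize. Counters are not
propagated to ancestors (importance comparisons are between the taxa of
competing records, which are leaves of the same kind); an explicit
subtree aggregate (`subtree_cds_count()`) exists for rank-level
reporting. Records whose taxon is absent from the taxonomy keep their
data but report importance 0, so they sort last — information is
preserved, never silently preferred. `merged.dmp` handling is out of
scope.

## 3. The store

The store is an in-memory indexed table with single-file persistence,
exposing exactly the retrieval contract the pipeline needs: lookup by
versioned accession (exact), unversioned accession (latest stored
version), GI (tried first for all-digit tokens), and protein/DNA MD5
with optional taxon restriction (the compound index). Insertion is
latest-wins on the accession stem (accession minus its `.N` version), so
only the newest version of an entry is retained — which is also why GI
lookups can go stale, and why accessions are the recommended identifier.

## 4. Resolution of user input

Input is an identifier list (one per line) or FASTA; FASTA is detected
by a leading `>`. A sequence whose characters are ≥90% `A/C/G/T/N/U` is
treated as DNA, otherwise protein — the 90% threshold tolerates sparse
ambiguity codes in real nucleotide data while virtually no protein
reaches it. Resolution order per item:

1. identifiers from the header, accessions before GIs;
2. failing that, the MD5 of the uppercased sequence, protein index
   first, then DNA (fixed order; for the rare sequence valid in both
   alphabets a protein interpretation is likelier for real input, and a
   fixed order keeps resolution deterministic);
3. failing that, the sequence passes through as provided — no
   annotation, except taxonomy when a `[Species name]` bracket on the
   title line resolves (exact, case-insensitive match on scientific or
   common name; an unmatched hint disables the restriction with a
   warning rather than failing the item).

A bare sequence matching several records within the allowed taxon scope
admits *all* of them into the pipeline; redundancy control downstream
decides what survives. Identifier-only items that match nothing are
reported unresolved; failures are data, never exceptions.

## 5. Expansion, clustering, quality, representatives

**Expansion** recovers diversity that non-redundant protein databases
collapse: `full` appends every store record sharing the protein hash
(all taxa — full taxonomic coverage plus all synonymous CDS);
`cds_within_taxon` restricts to the record's own taxon (synonymous CDS
only). Overlapping expansions keep each record once, at first
appearance, inheriting the ordinal of the input item that pulled it in.

**Clustering** partitions the (expanded) records by one key: accession
(default — each accession once), protein or DNA hash (NR-style
merging; the DNA level yields a non-redundant CDS set after synonymous
expansion), hash-plus-taxon (duplicates in different taxa retained), or
the taxon of the lineage ancestor at a requested rank — one sequence per
genus/family/order, the phylogenetics use case. A record whose lineage
lacks the requested rank clusters alone under its own taxon rather than
being discarded.

**Quality flags** per member: incomplete N terminus (`partial5`),
incomplete C terminus (`partial3`), ambiguous DNA, ambiguous protein,
and length outside a user range. A member *passes* when no enabled flag
is set; the default enables the first four. Length (and the
best-effort residue count below) are evaluated on the output sequence
kind — DNA when DNA or wobble output is requested, protein otherwise —
since that is the sequence whose quality the user will consume.
Passthrough records have unknown completeness (flags false) and
computed ambiguity.

**Representative selection.** Candidates are the passing members; one
candidate wins outright. Several are ordered by a single lexicographic
tuple, maximizing in order: species importance, RefSeq membership,
store-wide protein representation count (computed at query time), CDS
length, source entry length; final tie-break is minimal input position.
The tuple sort is equivalent to the sequential filter-until-one reading
for totally ordered keys and is what the test oracle implements
independently. When *no* member passes, the default (`best_effort`)
picks the member with the most non-ambiguous residues in the output
kind — rejecting imperfect sequences only when a superior equivalent
exists — while `drop` leaves the cluster unrepresented.

## 6. Labels and output

Each output record gets a dictionary: identifiers (`acv`, `gi`,
`taxID`), names (`SciName`; `ComName` falling back to `SciName` when the
taxon has no common name), annotation (`gene`, `product`, ...), every
rank present in the lineage as its own key (`order`, `family`, ...),
`genus` and `species` (the specific epithet — the species binomial minus
its leading genus, so `%(genus).1s%(species)s` renders `Hsapiens`),
`sqNr`, `today` (injectable for reproducible output), `pcGC`, `length`
and `origLabel`. Templates use the printf-style subset
`%(key)s`, `%(key).Ns` (truncate), `%(key)M.Nf` (fixed-point) — the
subset the worked examples exercise; restricting the mini-language keeps
templates portable and total (unknown keys render empty with a warning,
never aborting a batch). A stray space before the conversion character
(`%(genus).1 s`) is tolerated.

Label finalization: optional strict charset (anything outside
`[A-Za-z0-9_.-]` becomes `_`, a leading FASTA `>` excepted), truncation
to the length cap, then uniquification by appending `_2`, `_3`, ... to
repeats (first occurrence unchanged; the suffix may exceed the cap —
uniqueness trumps the cap because duplicate tree labels are fatal
downstream while an over-long one is merely ugly).

Sequence representations: protein, DNA, `wobble_ry` (third codon
position recoded to `R` (purine), `Y` (pyrimidine), `N` otherwise, with
`R`/`Y` as fixed points so the recoding is idempotent), a whole-sequence
`ry` recoding offered as an extension, and `none` — which switches the
writer from 60-column FASTA to `label<TAB>comment` lines, the labeled
property file format consumed by tree relabeling/annotation tools.

## 7. Synthetic fixtures: what they emulate, what they do not

`make_taxdump()`/`make_genbank()` generate the test substrate: a fixed
toy taxonomy backbone (human with genus/family/order lineage and common
name, a second hominid, a rodent, a virus without a common name, plus
optional random species) and GenBank entries whose CDS span the
strand × splice × partial × pseudo × no-translation × ambiguity grid.
Defaults: 25 entries, up to 4 CDS each, 15% partial at either end, 10%
pseudo, 10% translation-less, 15% ambiguous, half minus-strand, half
spliced — partial and defect rates chosen high enough that every code
path appears in a modest fixture, an order of magnitude above their
frequency in curated divisions. The generator writes the ground truth
(expected spliced DNA, translation, flags, taxon) alongside the files,
so parser tests assert field-by-field against the generator, and an
independent third-party parser provides a second opinion in the test
suite.

What the fixtures do *not* emulate: real codon usage or homology
(sequences are random codons, so translations can contain internal `*`
and wobble-position `N`s appear as `X`), multi-isoform gene structure,
annotation inconsistencies between `/translation` and the located DNA,
and GenBank-scale volume. Passing tests therefore demonstrate contract
correctness on well-formed (if adversarially varied) input, not
robustness to the full zoo of historical GenBank irregularities.

Test and example problem sizes — a 100-entry fixture file (~250 CDS),
1,000 random clusters of ≤8 members against the selection oracle,
10,000 random label lists — were chosen as the smallest sets that
exercise every branch with comfortable margins while keeping the whole
suite fast to run routinely.

## 8. Numerical and degenerate-input choices

* MD5 collisions are ignored as a risk (no adversarial input; 2⁻¹²⁸).
* Empty sequences are rejected at hashing and GC computation; empty
  selections are an error, but an empty *pipeline result* is legal and
  reported, and writing zero records succeeds.
* `percent_gc` is exact rational arithmetic in doubles; the only
  rounding is at rendering (`%.2f`).
* Ties everywhere break toward input order, making every stage
  deterministic given the store; with a pinned `today`, identical
  invocations are byte-identical.
* GIs are stored as strings (real GIs exceed 32-bit integers).
* Re-ingesting a replaced accession increments the taxon counter again;
  counters are an interest *proxy*, and full rebuilds (the supported
  mode) never re-insert.

## 9. Known limitations

* No similarity-threshold clustering: redundancy here is exact identity
  or taxonomy, by design; identity-threshold tools solve a different
  problem.
* No ASN.1/XML parsing, no WGS/RefSeq download logistics, no
  incremental daily updates — builds are full rebuilds from local flat
  files.
* The annotation dictionary covers the documented keys plus all lineage
  ranks; the original web system exposed supplementary keys whose full
  inventory is not reconstructable, so templates relying on exotic keys
  render them empty (with a warning) rather than failing.
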