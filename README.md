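# cdskit

Taxonomy-aware extraction, selection, de-duplication and relabeling of
protein-coding sequences (CDS), in R.

## The problem

Comparative studies — molecular phylogeny, positive-selection scans,
structure–function analyses — need curated sets of protein-coding DNA
and/or amino acid sequences. Assembling such a set by hand means mapping
protein identifiers back to the nucleotide entries that contain their CDS,
weeding out partial or ambiguous sequences, collapsing redundancy (or
deliberately recovering it: identical proteins in other species,
synonymous CDS for the same protein), picking a sensible representative
for every cluster, and renaming everything so downstream tree software
does not choke. `cdskit` automates that workflow end to end on a local,
indexed store built from GenBank flat files and an NCBI taxonomy dump.

Key capabilities:

* **Ingest** — parse GenBank flat files into one record per annotated CDS
  (pseudo genes and CDS without `/translation` excluded), extracting the
  spliced coding-strand sequence from `join`/`complement` locations and
  flagging incomplete 5′/3′ ends from the `<`/`>` markers of the feature
  location, the only reliable signal of partialness.
* **Index** — records are retrievable by protein accession (versioned or
  not; latest version wins), GI, and MD5 hashes of the uppercased protein
  and DNA sequences, optionally compounded with the taxonomy id.
* **Resolve** — user input is an identifier list or FASTA; NCBI-style
  headers contribute identifiers, a `[Species name]` bracket restricts
  sequence-hash matches to that taxon, and unmatched sequences pass
  through unannotated rather than being dropped.
* **Expand** — from one protein to all identical proteins in all taxa
  (`full`) or all synonymous CDS within its taxon (`cds_within_taxon`).
* **Cluster & filter** — redundancy by accession, protein/DNA sequence
  identity (optionally per taxon), or by the ancestor at any taxonomic
  rank (one sequence per genus, family, ...). Members are quality-flagged
  (incomplete N/C terminus, ambiguous DNA or protein residues, length out
  of range).
* **Represent** — each cluster is represented by the best member, chosen
  lexicographically on: species importance (number of annotated CDS for
  the taxon, a proxy for how well-studied it is), RefSeq membership,
  how often the protein sequence occurs in the store, CDS length, source
  entry length, and finally input order.
* **Format** — FASTA output as protein, DNA, or R/Y wobble-recoded DNA
  (third codon position → purine/pyrimidine), with labels from presets or
  printf-style templates over a rich per-record dictionary
  (`%(ComName)s`, `%(family)s`, `%(pcGC)5.2f`, ...), sanitized, length-
  capped and uniquified; or two-column labeled property files for tree
  relabeling/annotation tools.

## Worked example

Everything below runs offline on synthetic fixtures the package
generates itself (the `cdskit` script lives in `inst/scripts/`; locate it
with `system.file("scripts", "cdskit", package = "cdskit")`).

```sh
cdskit make-fixtures --seed 42 --out fx
#> make-fixtures: 65 CDS in fx
cdskit build --genbank fx/fixture.gb --taxdump fx/taxdump --db demo.cdsdb --quiet
#> build: 50 records -> demo.cdsdb
printf 'SYN00001.1\nXP_000005.1\nSYN00007.1\n' > ids.txt
cdskit select --db demo.cdsdb --in ids.txt --seq aa \
    --label '>%(ComName)s_%(gene)s' --comment '[%(SciName)s] %(acv)s'
```

prints (report on stderr, FASTA on stdout):

```
select: 3 items, 3 matched, 0 passthrough, 0 unresolved; 3 expanded, 3 clusters (0 dropped), 3 written
>Tobacco mosaic virus_gene1 [Tobacco mosaic virus] SYN00001.1
MTLRRAXMTLAKLLWNTVGGLPKS
>house mouse_gene5 [Mus musculus] XP_000005.1
MFERYCDTSL*GDVPIETKSISDPGSSCPTYDLSKNEVSPRLVLRCLT
>chimpanzee_gene7 [Pan troglodytes] SYN00007.1
MLEAGPPSPGTLNGRITHCELRVVDTFNDF
```

65 CDS were generated, of which 50 are real (the rest are pseudo genes or
lack a translation and are skipped at build time). Each label is the
taxon common name (scientific name where none exists, as for the virus)
plus the gene, and the comment carries the species and accession. The
same selection as a labeled property file of GC content:

```sh
cdskit select --db demo.cdsdb --in ids.txt --seq none \
    --label '%(SciName)s' --comment '%(pcGC)5.2f'
```

```
Tobacco mosaic virus	49.33
Mus musculus	55.10
Pan troglodytes	53.76
```

The same pipeline is available directly in R (`build_store()`,
`run_pipeline()`, `format_records()`); see the methods vignette
(`vignettes/cdskit-methods.Rmd`) for the model behind each stage.

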