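# storfr

Finding genes between genes: stop-to-stop ORF discovery in the
unannotated regions of prokaryotic genomes.

Prokaryotic annotations cover most of the genome, but the leftover
unannotated regions (URs) routinely hide real coding sequence — genes
with non-canonical start codons that start-anchored predictors truncate
or drop, short proteins, and pseudogene fragments. `storfr` extracts
these regions from an annotated genome (FASTA + GFF3), scans them in all
six frames for **StORFs** — stop-to-stop open reading frames, i.e. the
in-frame interval between two consecutive stop codons — filters the
nested and heavily overlapping candidates, translates the survivors
under the bacterial genetic code (table 11, with no start-codon
rewriting), and writes them back into the annotation. A pangenome layer
parses two-round CD-HIT `.clstr` output and classifies gene families by
origin (annotated-only, annotated + StORF, StORF-bridged, StORF-only)
and prevalence (core ≥ 99%, soft-core ≥ 95%, accessory ≥ 15%, rare),
plus their spread across genera.

The method in one breath: annotation occupancy is the union of selected
feature spans; gaps ≥ 30 nt become URs, extended 50 nt into the flanking
genes (a minimal UR is 130 nt) and capped at 100 kb; within each UR,
every pair of consecutive same-frame stops on either strand is a StORF
candidate; candidates of 100–50 000 nt are kept, then greedily filtered
by descending length, discarding any candidate overlapping a longer
retained one by more than 50 nt.

Who it is for: anyone holding an annotated bacterial or archaeal genome
(Ensembl-style, or CDS-only predictor output) who wants a systematic,
start-codon-agnostic sweep of what the annotation missed — and, with
CD-HIT cluster files, what those misses do to a species' pangenome.

## Worked example

The synthetic module builds a fully specified genome with planted
("hidden") genes that are absent from its annotation, so the pipeline
can be demonstrated — and scored — without downloading anything:

```r
library(storfr)

g <- generate_genome(synthetic_genome_spec(
  n_annotated_genes = 12, n_hidden_genes = 4, seed = 3))
write_fasta(g$contigs, "ex.fa")
write_gff(g$features, "ex.gff3")

rep <- storf_report("ex.fa", "ex.gff3")
rep
#> StORF report
#>   contigs:             1
#>   annotation records: 12 (12 define occupancy)
#>   unannotated regions: 13
#>   StORFs retained:     4

rep$storfs[, c("id", "genome_start", "genome_end", "strand", "frame", "length")]
#>                       id genome_start genome_end strand frame length
#> 1  contig01_UR_4_StORF_1         1866       2141      +     3    276
#> 2  contig01_UR_5_StORF_1         3075       3299      -     6    225
#> 3  contig01_UR_7_StORF_1         4570       4869      +     3    300
#> 4 contig01_UR_10_StORF_1         7560       7766      -     5    207
```

The 12 annotated genes leave 13 gaps of at least 30 nt; after extension
each becomes a UR, and exactly four URs yield a StORF of at least
100 nt — one per planted gene, on the planted strand and frame, spanning
the planted stop-to-stop interval. Scoring against the generator's truth
table at the standard 75% in-frame coverage criterion confirms it:

```r
evaluate_recovery(g$truth, rep$storfs)$summary
#> $n_truth:    4
#> $n_detected: 4
#> $n_missed:   0
#> $n_surplus:  0
#> $recovery:   1
```

`rep$enhanced` is the original annotation with four `ORF` records added
(source `StORF-Reporter`, attribute `StORF_Type=StORF`); the original
records are preserved byte-for-byte, and `extract_storfs_from_gff()`
pulls the StORFs back out of the enhanced file, sequences included.

A command-line front end with the same operations (`ur-extract`,
`storf-find`, `report`, `extract-storfs`, `pangenome`, `simulate`) ships
in `inst/cli/storfr.R`:

```sh
Rscript inst/cli/storfr.R report --fasta ex.fa --gff ex.gff3 \
    --out-gff enhanced.gff3
```

See `vignette("storf-discovery")` for the model, the parameter
rationale (the 30/50/100k UR rules, the 100 nt floor, the strict >50 nt
overlap rule), coordinate conventions, the pangenome classification, and
what the synthetic benchmarks do and do not demonstrate.

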