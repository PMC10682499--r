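---
title: "Stop-to-stop ORF discovery in unannotated genome regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stop-to-stop ORF discovery in unannotated genome regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(storfr)
```

## The problem

Prokaryotic genomes are densely annotated — typically 85–90% of the
sequence is covered by gene records — yet the residual unannotated
regions (URs) are not empty. They hold genes with non-canonical start
codons that start-anchored predictors truncate or skip outright,
pseudogene fragments, short proteins below common length cut-offs, and
genuinely novel coding sequence. `storfr` systematically interrogates
these regions.

The central object is the **StORF** (stop-to-stop open reading frame):
the in-frame interval between two consecutive stop codons of a reading
frame. Unlike the usual start-to-stop ORF, a StORF needs no start-codon
call. Stop codons terminate nearly all coding sequences in nearly all
prokaryotes, so the downstream boundary is reliable; the upstream
in-frame stop necessarily lies upstream of any usable start codon, so a
StORF over-covers its gene by a short untranslated stretch rather than
risking truncation. The cost is deliberate: the reported interval
includes a 5' margin whose length is the distance from the upstream stop
to the true initiation site.

## The procedure

1. **UR extraction** (`extract_unannotated_regions()`). Annotation
   occupancy is the union of the selected feature spans (by default every
   `gene` record, coding or not; CDS-only annotations use a `CDS`
   selector). Gaps of at least `min_gap = 30` nt are kept — shorter gaps
   cannot hold anything of interest and mostly reflect packing between
   adjacent genes. Each kept gap is extended by `extension = 50` nt into
   the flanking annotation on both sides (clamped at contig ends), so a
   minimal UR is 130 nt. The 50 nt figure is motivated by two empirical
   distributions over curated bacterial annotations: the median overlap
   between adjacent annotated genes is about 4 nt with the bulk below
   50 nt, and the median distance from an annotated start codon to its
   first in-frame upstream stop is about 39 nt. Fifty nucleotides
   therefore captures both a gene's true overlap into the gap and the
   untranslated head of a StORF. Both statistics are recomputable with
   `gene_overlap_lengths()` and `upstream_stop_distances()`. Extended
   regions longer than `max_ur_len = 100` kb are discarded: a gap that
   size is either an assembly/annotation defect or deserves manual
   attention, not silent ORF calling.

2. **StORF enumeration** (`enumerate_storfs()`). Each UR and its reverse
   complement are scanned in all three frames; every pair of consecutive
   same-frame stops defines a candidate spanning both delimiting stops.
   Candidates shorter than `min_storf_len = 100` nt (33 aa) or longer
   than `max_storf_len = 50` kb are dropped. The 100 nt floor is a noise
   control, not a biological claim — random sequence is riddled with
   short stop-free intervals — and is freely adjustable.

3. **Con-StORF joining** (`join_con_storfs()`, off by default). Runs of
   consecutive same-frame StORFs share their delimiting stops; joining
   them can reassemble a gene split by a premature stop mutation or by
   stop-codon recoding (e.g. TGA read as tryptophan). Every window of
   consecutive candidates spanning at most `max_stops_spanned = 4` stops
   is emitted alongside the plain StORFs; internal stops translate as
   `*`. Con-StORFs never feed the overlap/upstream-distance statistics.

4. **Overlap filtering** (`filter_storfs()`). Unfiltered six-frame
   enumeration reports heavily nested and overlapping candidates.
   Candidates of one UR are sorted by length descending and accepted
   greedily; a candidate is rejected if it overlaps an accepted one by
   more than `max_overlap = 50` nt. Overlap is measured on forward-UR
   spans regardless of strand or frame, so nested candidates always
   lose. Ties in length break by smaller UR start, then smaller frame
   index, making output deterministic. The comparison is strict
   (`> 50` removes), so two StORFs overlapping exactly 50 nt coexist.
   Filtering is per-UR only; StORFs of different URs are never compared,
   even when their extended spans overlap on the genome.

5. **Translation** (`translate_storf()`). The interval between the
   delimiting stops is translated with the bacterial/archaeal genetic
   code (table 11) with no start-codon special-casing: a GTG or TTG that
   may in fact initiate translation is reported as V or L, because the
   initiation site is unknown and rewriting it would be a guess. Codons
   containing IUPAC ambiguity codes translate to `X`; stop-codon
   matching during enumeration is exact, so ambiguous codons never count
   as stops.

6. **Supplementation** (`supplement_annotation()`,
   `extract_storfs_from_gff()`). Retained StORFs are merged into the
   original GFF3 as `ORF` records from source `StORF-Reporter` with a
   `StORF_Type` attribute; original records are preserved byte-for-byte
   (the parser retains each input line verbatim). A `prokka_like`
   dialect emits `CDS`-typed records instead for downstream pangenome
   tools that only ingest CDS features. Extraction inverts
   supplementation exactly and can reconstruct DNA/protein from the
   genome.

## Coordinate conventions

GFF3 is 1-based inclusive at every file boundary. Internally, interval
arithmetic uses 0-based half-open spans; conversion happens only in the
IO layer and in `to_genome_coordinates()`. StORF records carry both the
UR-relative span (0-based half-open on the forward UR sequence) and the
genome span (1-based inclusive on the forward strand), with frames 1–3
forward and 4–6 reverse. Slicing the genome at the reported span (and
reverse-complementing for `-`) reproduces the stored DNA exactly; the
test suite asserts this on seeded genomes.

Degenerate inputs are handled conservatively: features extending past
their contig are a hard error rather than being clamped (they indicate
malformed input); unknown (`.`) strands count as annotated occupancy
(URs are strand-agnostic); gaps at contig ends are eligible URs whose
extension clamps at the boundary, and the 130 nt total minimum is not
re-checked after clamping — the ≥ 30 nt gap rule governs.

## Pangenome classification

`build_pangenome()` interprets a two-round CD-HIT protein clustering:
round 1 clusters the annotated proteins of all genomes; round 2 clusters
the round-1 representatives together with the StORF proteins (the `.clstr`
files are parsed, CD-HIT itself is external). Round-2 members that are
round-1 representatives are expanded back into their full round-1
memberships, after which each family is classified twice:

* **Origin type** — `Ensembl-Only` (no StORF member), `Ensembl-StORF`
  (both kinds), `StORF-Combined-Ensembl` (the cluster holds two or more
  round-1 representatives, i.e. StORFs bridged formerly distinct
  annotated families) or `StORF-Only`. StORF membership is detected by
  the literal `StORF` tag in the sequence id, which is why the package's
  id scheme embeds it.
* **Prevalence** — the fraction of unique genomes contributing a member:
  core at ≥ 99%, soft-core at ≥ 95%, accessory at ≥ 15%, and an explicit
  `rare` band below that (left unnamed in common usage). Duplicate
  members from one genome count once. The `StORF` summary row re-counts
  every mixed family by its StORF members alone, showing which families
  owe their prevalence to StORFs; we apply it to both `Ensembl-StORF`
  and `StORF-Combined-Ensembl` families, since both contain annotated
  and StORF sequences.

Genome labels follow the `genome|protein` id convention; the genus is
the genome label's first underscore-delimited token unless an explicit
genome-to-genus map is supplied. `genera_spread()` tabulates families by
type and number of genera (1–6, >6), excluding single-sequence
StORF-Only clusters, which are uninformative.

## What the synthetic generator emulates — and what it does not

`generate_genome()` builds contigs as alternating intergenic filler and
annotated genes, with a subset of gaps hosting *hidden* genes: stop-
delimited, internally stop-free sequences planted on alternating strands
and deliberately absent from the emitted GFF. Defaults (30 annotated
genes of 300–900 nt, gaps of 60–240 nt, GC 0.5, one contig) give the
high gene density and UR length profile typical of bacterial genomes at
desk scale; all sizes are parameters of `synthetic_genome_spec()`.

Two constructions make the truth table airtight:

* Filler carries a 15 nt *stop cassette* (`TAATTAATTAATTAA`, which
  contains a stop in all six frames) at its start, its end, and at least
  every 45 nt. Any stop-free run through a UR is therefore bounded by
  roughly the 50 nt flank plus one cassette period — well under the
  100 nt StORF floor — so filler can never produce a qualifying StORF.
* Hidden-gene bodies interleave a recurring codon-aligned salt motif
  (`TTA ATA ATT AAC TAC`: stop-free in the coding frame, stops in the
  other five frames) with random non-stop codons, so no off-frame decoy
  longer than the gene itself can arise and out-compete it in the
  overlap filter.

Consequently, on well-separated specs the planted-gene recovery of the
full pipeline is exactly 100% at the standard 75% in-frame coverage
detection criterion (`evaluate_recovery()`), with zero surplus StORFs —
and the test suite asserts precisely that. What passing these tests does
**not** show: performance on real genomes, where URs contain genuine
stop-free runs that are not genes (the filter and length floor only
mitigate this), codon usage and GC skew are structured, assemblies carry
ambiguity codes and fragmentation, and annotation completeness varies.
The generator makes no attempt at realistic codon usage, pseudogene
mutation processes, or inter-genome homology.

`generate_clstr_fixture()` plays the same role for the pangenome layer:
it emits syntactically valid two-round `.clstr` text for a declared
family structure together with the classification each family must
receive, so the classifier can be checked against construction truth,
including the band edges at 169 genomes (169, 168 → core; 161 →
soft-core; 30 → accessory; 10 → rare) and representative-bridging
families.

## Numerical and design choices

* Overlap comparison in the filter is strictly greater-than 50 nt; the
  boundary case is retained on both sides.
* Adjacent URs closer than twice the extension yield extended spans that
  overlap each other; each UR is processed independently and no merging
  occurs.
* The upstream-stop distance convention counts the nucleotides strictly
  between the stop codon's last base and the start codon's first base,
  so an abutting stop scores 0. Features whose start is within 3 nt of
  the contig edge are skipped and tallied separately from features with
  no upstream in-frame stop at all.
* The overlap statistic for adjacent annotated genes is the length of
  the intersection of consecutive spans (a nested gene contributes its
  full length).
* Problem sizes in the shipped tests and acceptance script — two contigs,
  30 annotated plus 20 planted genes (~30 kb), 100-UR oracle sweeps at
  ≤ 2 kb, 200-family cluster fixtures — were chosen as the smallest sizes
  at which every rule (both band edges, both strands, all six frames,
  bridging) is exercised.

## Limitations

* Selenocysteine/pyrrolysine recoding and condition-dependent stop
  read-through are out of scope; Con-StORF joining is the only
  concession to broken reading frames.
* No ribosome-binding-site or start-codon scoring is attempted; a StORF
  is a candidate region, not a gene call.
* The pangenome layer classifies an existing clustering; it does not
  cluster, align, or validate sequences itself.
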