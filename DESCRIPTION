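Package: storfr
Title: Stop-to-Stop Open Reading Frame Discovery in Unannotated Regions
    of Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts unannotated regions (URs) from annotated prokaryotic
    genomes, enumerates stop-to-stop open reading frames (StORFs) within them
    in all six frames, filters nested and heavily overlapping candidates,
    translates them under the bacterial genetic code (table 11) without
    rewriting alternative start codons, and supplements the source GFF3
    annotation with the retained StORFs.  A pangenome layer parses CD-HIT
    cluster files and classifies gene families by origin (annotated-only,
    annotated-plus-StORF, StORF-bridged, StORF-only) and prevalence (core,
    soft-core, accessory, rare), and tallies their spread across genera.  A
    synthetic-genome module generates annotated genomes with planted
    stop-delimited genes and scores their recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
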