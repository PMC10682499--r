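# Annotation supplementation: merge retained StORFs into an existing GFF3
# annotation, and extract them back out of an enhanced annotation.

#' Output dialect for supplemented annotations
#'
#' Controls the GFF record shape used for StORFs.  The default emits
#' `ORF`-typed records; `prokka_like` emits `CDS`-typed records so that
#' downstream pangenome tools (Roary, Panaroo, ...) that only ingest CDS
#' features can consume the file.  Either way the records carry
#' `StORF_Type` in their attributes, which marks their origin.
#'
#' @param name `"ensembl"` or `"prokka_like"`.
#' @param storf_feature_type Feature type for StORF records; defaults to
#'   `"ORF"` for `ensembl` and `"CDS"` for `prokka_like`.
#' @return An `annotation_dialect` object.
#' @export
annotation_dialect <- function(name = c("ensembl", "prokka_like"),
                               storf_feature_type = NULL) {
  name <- match.arg(name)
  if (is.null(storf_feature_type)) {
    storf_feature_type <- if (name == "prokka_like") "CDS" else "ORF"
  }
  if (!nzchar(storf_feature_type)) {
    stop("storf_feature_type must be non-empty", call. = FALSE)
  }
  structure(list(name = name, storf_feature_type = storf_feature_type),
            class = "annotation_dialect")
}

.storf_gff_records <- function(storfs, dialect) {
  if (!nrow(storfs)) return(.empty_gff())
  data.frame(
    contig = storfs$contig, source = "StORF-Reporter",
    type = dialect$storf_feature_type,
    start = storfs$genome_start, end = storfs$genome_end,
    score = ".", strand = storfs$strand, phase = ".",
    attributes = vapply(seq_len(nrow(storfs)), function(i) {
      gff_attributes(ID = storfs$id[i], UR = storfs$ur_id[i],
                     Frame = storfs$frame[i],
                     UR_Start = storfs$ur_start[i],
                     UR_End = storfs$ur_end[i],
                     StORF_Type = storfs$storf_type[i],
                     Stops_Spanned = storfs$stops_spanned[i])
    }, character(1)),
    raw = NA_character_,
    stringsAsFactors = FALSE)
}

#' Supplement an annotation with retained StORFs
#'
#' Appends one GFF record per StORF to the original feature set and sorts
#' the whole by (contig, start, end).  Original records are never edited:
#' rows read from file keep their verbatim `raw` line, so writing the
#' merged set reproduces them byte-identically.
#'
#' @param original_features Feature data frame from [read_gff()] with no
#'   selector (the full annotation).
#' @param storfs Retained StORF data frame from [find_storfs()], carrying
#'   genome coordinates.
#' @param dialect An [annotation_dialect()].
#' @param contig_ids Optional character vector of known contig ids; by
#'   default the contigs present in `original_features`.  A StORF on a
#'   contig outside this set is an error.
#' @return Merged feature data frame.
#' @export
supplement_annotation <- function(original_features, storfs,
                                  dialect = annotation_dialect(),
                                  contig_ids = NULL) {
  stopifnot(inherits(dialect, "annotation_dialect"))
  if (is.null(contig_ids)) {
    contig_ids <- unique(original_features$contig)
  }
  if (nrow(storfs)) {
    unknown <- setdiff(unique(storfs$contig), contig_ids)
    if (length(unknown)) {
      stop("StORF(s) on contig(s) absent from the annotation: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  orig <- original_features
  if (!"raw" %in% names(orig) && nrow(orig)) {
    orig$raw <- NA_character_
  }
  merged <- rbind(orig[, c(.gff_columns, "raw")],
                  .storf_gff_records(storfs, dialect))
  merged <- merged[order(merged$contig, merged$start, merged$end), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Extract StORF records from an enhanced annotation
#'
#' Returns exactly the records whose source is `StORF-Reporter` or whose
#' attributes carry a `StORF_Type` marker.  With the genome available, the
#' DNA and protein sequences are reconstructed from the reported spans.
#'
#' @param features Feature data frame from [read_gff()] on a supplemented
#'   annotation.
#' @param contigs Optional named character vector of contig sequences; when
#'   given, `dna` (read 5'→3' on the StORF's strand) and `protein` columns
#'   are reconstructed.
#' @param params A [storf_params()] object (for translation).
#' @return Data frame of StORF stubs: `id`, `contig`, `start`, `end`,
#'   `strand`, `storf_type`, `frame`, `ur_id`, `attributes`, and sequences
#'   when `contigs` is supplied.  Empty when the annotation holds none.
#' @export
extract_storfs_from_gff <- function(features, contigs = NULL,
                                    params = storf_params()) {
  sel <- features$source == "StORF-Reporter" |
    !is.na(gff_attr(features, "StORF_Type"))
  hits <- features[sel, , drop = FALSE]
  out <- data.frame(
    id = gff_attr(hits, "ID"),
    contig = hits$contig,
    start = hits$start, end = hits$end,
    strand = hits$strand,
    storf_type = gff_attr(hits, "StORF_Type"),
    frame = suppressWarnings(as.integer(gff_attr(hits, "Frame"))),
    ur_id = gff_attr(hits, "UR"),
    attributes = hits$attributes,
    stringsAsFactors = FALSE)
  if (!is.null(contigs) && nrow(out)) {
    unknown <- setdiff(unique(out$contig), names(contigs))
    if (length(unknown)) {
      stop("StORF(s) on contig(s) absent from the sequence set: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    dna <- vapply(seq_len(nrow(out)), function(i) {
      s <- substr(contigs[[out$contig[i]]], out$start[i], out$end[i])
      if (identical(out$strand[i], "-")) .revcomp_chr(s) else s
    }, character(1))
    out$dna <- dna
    out$protein <- vapply(dna, translate_storf, character(1),
                          params = params, USE.NAMES = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Run the full annotation-enhancement pipeline
#'
#' Reads a genome FASTA and its GFF3 annotation, extracts unannotated
#' regions using the selected occupancy features, finds and filters StORFs
#' in them, and merges the retained StORFs back into the full annotation.
#'
#' @param fasta_path Genome FASTA path.
#' @param gff_path Annotation GFF3 path.
#' @param selector [feature_selector()] defining annotation occupancy
#'   (default: records of type `gene`).
#' @param ur_parameters A [ur_params()] object.
#' @param storf_parameters A [storf_params()] object.
#' @param dialect An [annotation_dialect()].
#' @return A `storf_report` list with elements `contigs`, `features` (the
#'   full original annotation), `selected` (the occupancy subset), `urs`,
#'   `storfs` and `enhanced` (the supplemented annotation).
#' @export
storf_report <- function(fasta_path, gff_path,
                         selector = feature_selector(),
                         ur_parameters = ur_params(),
                         storf_parameters = storf_params(),
                         dialect = annotation_dialect()) {
  contigs <- read_fasta(fasta_path, alphabet = "dna")
  features <- read_gff(gff_path)
  selected <- .apply_selector(features, selector)
  urs <- extract_unannotated_regions(contigs, selected, ur_parameters)
  storfs <- find_storfs(urs, storf_parameters)
  enhanced <- supplement_annotation(features, storfs, dialect,
                                    contig_ids = names(contigs))
  structure(list(contigs = contigs, features = features,
                 selected = selected, urs = urs, storfs = storfs,
                 enhanced = enhanced),
            class = "storf_report")
}

#' @export
print.storf_report <- function(x, ...) {
  cat("StORF report\n")
  cat("  contigs:            ", length(x$contigs), "\n")
  cat("  annotation records: ", nrow(x$features),
      " (", nrow(x$selected), " define occupancy)\n", sep = "")
  cat("  unannotated regions:", nrow(x$urs), "\n")
  cat("  StORFs retained:    ", nrow(x$storfs), "\n")
  invisible(x)
}
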