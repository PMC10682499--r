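# Unannotated-region (UR) extraction and the annotation statistics used to
# parameterise the flanking extension.

#' Parameters for unannotated-region extraction
#'
#' @param min_gap Minimum length (nt) of an inter-annotation gap for it to
#'   be extracted (default 30).
#' @param extension Flanking extension (nt) applied to both ends of an
#'   extracted gap, reaching into the neighbouring annotation (default 50);
#'   it captures gene overlaps and the untranslated stretch between a
#'   StORF's upstream stop and the true start codon.
#' @param max_ur_len Maximum extended UR length (nt); longer regions are
#'   discarded as likely annotation error (default 100000).
#' @return A validated `ur_params` object.
#' @export
ur_params <- function(min_gap = 30, extension = 50, max_ur_len = 100000) {
  stopifnot(min_gap >= 0, extension >= 0, max_ur_len > 0)
  if (max_ur_len <= min_gap + 2 * extension) {
    stop("max_ur_len must exceed min_gap + 2*extension", call. = FALSE)
  }
  structure(list(min_gap = as.integer(min_gap),
                 extension = as.integer(extension),
                 max_ur_len = as.integer(max_ur_len)),
            class = "ur_params")
}

#' Merged annotated intervals on one contig
#'
#' Unions all feature spans on a contig into disjoint 0-based half-open
#' intervals; overlapping and abutting spans are merged.
#'
#' @param features Feature data frame (see [read_gff()]); only rows on
#'   `contig_id` are used and all rows must lie on it.
#' @param contig_id Contig to compute intervals for.
#' @param contig_length Length of the contig (nt); features extending past
#'   it are an error (malformed annotation).
#' @return Data frame with 0-based half-open `start`, `end` columns.
#' @export
annotated_intervals <- function(features, contig_id, contig_length) {
  feats <- features[features$contig == contig_id, , drop = FALSE]
  if (nrow(feats) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  if (any(feats$end > contig_length) || any(feats$start < 1L)) {
    bad <- feats[feats$end > contig_length | feats$start < 1L, , drop = FALSE]
    stop("feature span [", bad$start[1], ",", bad$end[1],
         "] outside contig ", contig_id, " (length ", contig_length, ")",
         call. = FALSE)
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = feats$start, end = feats$end))
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Extract unannotated regions from an annotated genome
#'
#' Computes the gaps between merged annotation intervals on every contig
#' (gaps at contig ends included).  Gaps of at least `min_gap` nt are
#' extended by `extension` nt into the flanking annotation on both sides,
#' clamped to the contig bounds; extended regions longer than `max_ur_len`
#' are discarded.
#'
#' @param contigs Named character vector of contig sequences (uppercase
#'   DNA), as returned by [read_fasta()].
#' @param features Feature data frame, already restricted to the feature
#'   types that define occupancy (see [feature_selector()]).
#' @param params A [ur_params()] object.
#' @return Data frame with one row per UR: `id` (`"<contig>_UR_<n>"`, `n`
#'   restarting at 1 per contig), `contig`, 1-based inclusive `gap_start`,
#'   `gap_end` (the un-extended gap), `ext_start`, `ext_end` (after
#'   extension and clamping), `length` (extended length) and `sequence`.
#' @export
extract_unannotated_regions <- function(contigs, features,
                                        params = ur_params()) {
  stopifnot(inherits(params, "ur_params"))
  unknown <- setdiff(unique(features$contig), names(contigs))
  if (length(unknown)) {
    stop("features reference contig(s) absent from the sequence set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (cid in sort(names(contigs))) {
    len <- nchar(contigs[[cid]])
    ann <- annotated_intervals(features, cid, len)
    whole <- IRanges::IRanges(start = 1L, end = len)
    occupied <- IRanges::IRanges(start = ann$start + 1L, end = ann$end)
    gaps <- IRanges::setdiff(whole, occupied)
    if (!length(gaps)) next
    gs <- IRanges::start(gaps)
    ge <- IRanges::end(gaps)
    big <- (ge - gs + 1L) >= params$min_gap
    gs <- gs[big]
    ge <- ge[big]
    if (!length(gs)) next
    es <- pmax(1L, gs - params$extension)
    ee <- pmin(len, ge + params$extension)
    fits <- (ee - es + 1L) <= params$max_ur_len
    if (any(!fits)) {
      message(sum(!fits), " UR(s) on ", cid, " exceeded max_ur_len (",
              params$max_ur_len, " nt) and were discarded: ",
              paste0("[", es[!fits], ",", ee[!fits], "]", collapse = " "))
    }
    gs <- gs[fits]; ge <- ge[fits]; es <- es[fits]; ee <- ee[fits]
    if (!length(gs)) next
    out[[cid]] <- data.frame(
      id = paste0(cid, "_UR_", seq_along(gs)),
      contig = cid,
      gap_start = gs, gap_end = ge,
      ext_start = es, ext_end = ee,
      length = ee - es + 1L,
      sequence = substring(contigs[[cid]], es, ee),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(id = character(), contig = character(),
                      gap_start = integer(), gap_end = integer(),
                      ext_start = integer(), ext_end = integer(),
                      length = integer(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write unannotated regions as GFF3 and FASTA
#'
#' @param urs UR data frame from [extract_unannotated_regions()].
#' @param gff_path,fasta_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, a list of the paths written.
#' @export
write_urs <- function(urs, gff_path = NULL, fasta_path = NULL) {
  if (!is.null(gff_path)) {
    feats <- data.frame(
      contig = urs$contig, source = "storfr",
      type = "unannotated_region",
      start = urs$ext_start, end = urs$ext_end,
      score = ".", strand = ".", phase = ".",
      attributes = vapply(seq_len(nrow(urs)), function(i) {
        gff_attributes(ID = urs$id[i], gap_start = urs$gap_start[i],
                       gap_end = urs$gap_end[i])
      }, character(1)),
      stringsAsFactors = FALSE)
    write_gff(feats, gff_path)
  }
  if (!is.null(fasta_path)) {
    seqs <- urs$sequence
    names(seqs) <- urs$id
    write_fasta(seqs, fasta_path)
  }
  invisible(list(gff = gff_path, fasta = fasta_path))
}

#' Overlap lengths between successive annotated features
#'
#' For each pair of features that are consecutive along a contig (sorted by
#' start), records the length of the intersection of their spans when they
#' overlap; abutting or disjoint pairs contribute nothing.  A feature nested
#' inside its predecessor contributes its full length.
#'
#' @param features Feature data frame.
#' @return Integer vector of overlap lengths (nt); summarise with
#'   [stats::median()].
#' @export
gene_overlap_lengths <- function(features) {
  if (nrow(features) < 2L) return(integer(0))
  feats <- features[order(features$contig, features$start, features$end), ,
                    drop = FALSE]
  res <- integer(0)
  for (cid in unique(feats$contig)) {
    f <- feats[feats$contig == cid, , drop = FALSE]
    if (nrow(f) < 2L) next
    i <- seq_len(nrow(f) - 1L)
    ov <- pmin(f$end[i], f$end[i + 1L]) - f$start[i + 1L] + 1L
    res <- c(res, ov[ov > 0L])
  }
  res
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Distance from annotated start codons to the first upstream in-frame stop
#'
#' For every feature, walks upstream of the annotated start codon
#' (strand-aware) in steps of 3 nt until a stop codon is found or the
#' contig end is reached.  The distance is the number of nucleotides
#' strictly between the last base of that stop codon and the first base of
#' the start codon, so a stop abutting the start scores 0.
#'
#' @param features Feature data frame (gene/CDS records with strand; `.`
#'   strands are treated as forward).
#' @param contigs Named character vector of contig sequences.
#' @param stop_codons Stop codon set (default `TAA`, `TAG`, `TGA`).
#' @return List with `distances` (integer vector, one entry per feature
#'   with an upstream in-frame stop), `n_skipped_edge` (features whose
#'   start is within 3 nt of the contig edge) and `n_no_stop` (features
#'   with no in-frame stop before the contig end).
#' @export
upstream_stop_distances <- function(features, contigs,
                                    stop_codons = c("TAA", "TAG", "TGA")) {
  distances <- integer(0)
  n_edge <- 0L
  n_no_stop <- 0L
  for (i in seq_len(nrow(features))) {
    cid <- features$contig[i]
    seq <- contigs[[cid]]
    if (is.null(seq)) {
      stop("feature on unknown contig: ", cid, call. = FALSE)
    }
    len <- nchar(seq)
    found <- NA_integer_
    if (!identical(features$strand[i], "-")) {
      s <- features$start[i]
      if (s - 3L < 1L) {
        n_edge <- n_edge + 1L
        next
      }
      k <- 1L
      repeat {
        p <- s - 3L * k
        if (p < 1L) break
        if (substr(seq, p, p + 2L) %in% stop_codons) {
          found <- 3L * (k - 1L)
          break
        }
        k <- k + 1L
      }
    } else {
      e <- features$end[i]
      if (e + 3L > len) {
        n_edge <- n_edge + 1L
        next
      }
      k <- 1L
      repeat {
        p <- e + 3L * k - 2L
        if (p + 2L > len) break
        if (.revcomp_chr(substr(seq, p, p + 2L)) %in% stop_codons) {
          found <- 3L * (k - 1L)
          break
        }
        k <- k + 1L
      }
    }
    if (is.na(found)) {
      n_no_stop <- n_no_stop + 1L
    } else {
      distances <- c(distances, found)
    }
  }
  list(distances = distances, n_skipped_edge = n_edge, n_no_stop = n_no_stop)
}
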