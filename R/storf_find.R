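# Stop-to-stop ORF (StORF) enumeration, joining, filtering, translation and
# genome-coordinate mapping.
#
# A StORF spans from the first base of its upstream stop codon to the last
# base of its downstream stop codon (both stops included); the protein is
# the translation of the interval between them.  UR-relative spans are
# 0-based half-open on the forward coordinates of the extended UR sequence,
# whatever the strand; genome spans are 1-based inclusive on the genome
# forward strand.  Frames 1-3 are the forward UR frames, 4-6 the reverse.

#' Parameters for StORF discovery
#'
#' @param stop_codons Set of stop codons (distinct DNA 3-mers).  The
#'   default is the three canonical stops; genomes that recode one (e.g.
#'   TGA read as tryptophan in *Mycoplasma*) can drop it.
#' @param min_storf_len Minimum StORF length in nt, stops included
#'   (default 100, i.e. 33 aa; suppresses spurious short frames).
#' @param max_storf_len Maximum StORF length in nt (default 50000; guards
#'   against run-on frames in low-complexity sequence).
#' @param max_overlap Maximum tolerated overlap (nt) between two retained
#'   StORFs of the same UR (default 50, matching the flanking extension).
#' @param report_con_storfs Also report consecutive StORFs joined across
#'   shared stop codons (Con-StORFs; default `FALSE`).
#' @param max_stops_spanned Maximum number of stop codons a Con-StORF may
#'   span, delimiting stops included (default 4).
#' @return A validated `storf_params` object.
#' @export
storf_params <- function(stop_codons = c("TAA", "TAG", "TGA"),
                         min_storf_len = 100, max_storf_len = 50000,
                         max_overlap = 50, report_con_storfs = FALSE,
                         max_stops_spanned = 4) {
  stop_codons <- toupper(stop_codons)
  if (!length(stop_codons) || any(nchar(stop_codons) != 3L) ||
      anyDuplicated(stop_codons) || any(grepl("[^ACGT]", stop_codons))) {
    stop("stop_codons must be distinct DNA 3-mers", call. = FALSE)
  }
  stopifnot(min_storf_len >= 6, min_storf_len <= max_storf_len,
            max_overlap >= 0, max_stops_spanned >= 2)
  structure(list(stop_codons = stop_codons,
                 min_storf_len = as.integer(min_storf_len),
                 max_storf_len = as.integer(max_storf_len),
                 max_overlap = as.integer(max_overlap),
                 report_con_storfs = isTRUE(report_con_storfs),
                 max_stops_spanned = as.integer(max_stops_spanned)),
            class = "storf_params")
}

#' Per-frame stop codon positions
#'
#' Scans a sequence for stop codons in the three frames of the given
#' strand.  Matching is exact: codons containing ambiguity codes never
#' match.
#'
#' @param seq DNA sequence (character scalar, uppercase).
#' @param stop_codons Stop codon set.
#' @return List of three ascending integer vectors of 0-based codon start
#'   offsets; element `f` holds the positions `p` with `p %% 3 == f - 1`.
#' @export
stop_positions <- function(seq, stop_codons = c("TAA", "TAG", "TGA")) {
  n <- nchar(seq)
  if (n < 3L) {
    return(list(integer(0), integer(0), integer(0)))
  }
  tri <- substring(seq, 1:(n - 2L), 3:n)
  p <- which(tri %in% stop_codons) - 1L
  lapply(0:2, function(f) p[p %% 3L == f])
}

.empty_storfs <- function() {
  data.frame(ur_id = character(), frame = integer(), strand = character(),
             ur_start = integer(), ur_end = integer(), length = integer(),
             storf_type = character(), stops_spanned = integer(),
             dna = character(), stringsAsFactors = FALSE)
}

# Core candidate generator.  `span_sizes` selects how many consecutive
# inter-stop intervals are joined: 1 gives plain StORFs, >=2 gives
# Con-StORFs.  Coordinates are reported on the forward UR sequence.
.storf_candidates <- function(ur_id, seq, params, span_sizes,
                              apply_length_filter = TRUE) {
  n <- nchar(seq)
  rows <- list()
  k <- 0L
  for (dir in c("+", "-")) {
    s <- if (dir == "+") seq else .revcomp_chr(seq)
    per_frame <- stop_positions(s, params$stop_codons)
    for (f in 1:3) {
      ps <- per_frame[[f]]
      if (length(ps) < 2L) next
      for (w in span_sizes) {
        if (length(ps) < w + 1L) next
        for (i in seq_len(length(ps) - w)) {
          a <- ps[i]
          b <- ps[i + w]
          len <- b + 3L - a
          if (apply_length_filter &&
              (len < params$min_storf_len || len > params$max_storf_len)) {
            next
          }
          if (dir == "+") {
            us <- a
            ue <- b + 3L
          } else {
            us <- n - (b + 3L)
            ue <- n - a
          }
          k <- k + 1L
          rows[[k]] <- data.frame(
            ur_id = ur_id,
            frame = if (dir == "+") f else f + 3L,
            strand = dir,
            ur_start = us, ur_end = ue, length = len,
            storf_type = if (w == 1L) "StORF" else "Con-StORF",
            stops_spanned = w + 1L,
            dna = substr(s, a + 1L, b + 3L),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!k) return(.empty_storfs())
  out <- do.call(rbind, rows)
  out <- out[order(out$ur_start, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.as_ur <- function(ur) {
  if (is.data.frame(ur)) {
    stopifnot(nrow(ur) == 1L)
    ur <- as.list(ur)
  }
  stopifnot(!is.null(ur$id), !is.null(ur$sequence))
  ur
}

#' Enumerate plain StORFs in one unannotated region
#'
#' Every pair of consecutive same-frame stop codons, on either strand,
#' defines a candidate spanning from the first base of the upstream stop to
#' the last base of the downstream stop.  Candidates outside
#' `[min_storf_len, max_storf_len]` are dropped (disable with
#' `apply_length_filter = FALSE`, e.g. before Con-StORF joining).
#'
#' @param ur A one-row UR data frame (see
#'   [extract_unannotated_regions()]) or a list with `id` and `sequence`.
#' @param params A [storf_params()] object.
#' @param apply_length_filter Apply the min/max length filter (default
#'   `TRUE`).
#' @return Unfiltered candidate data frame (see package conventions above);
#'   `dna` is read 5'→3' on the StORF's own strand.
#' @export
enumerate_storfs <- function(ur, params = storf_params(),
                             apply_length_filter = TRUE) {
  ur <- .as_ur(ur)
  .storf_candidates(ur$id, ur$sequence, params, span_sizes = 1L,
                    apply_length_filter = apply_length_filter)
}

#' Join consecutive StORFs into Con-StORFs
#'
#' Consecutive same-frame, same-strand StORFs share their delimiting stop
#' codons; joining a run of them captures genes fragmented by an internal
#' stop mutation or stop codon recoding.  Every contiguous window of two or
#' more consecutive candidates whose total stop count (delimiting stops
#' included) is at most `max_stops_spanned` is emitted; plain StORFs are
#' not removed by this step.
#'
#' @inheritParams enumerate_storfs
#' @return Data frame of Con-StORF records (empty when
#'   `max_stops_spanned <= 2`).
#' @export
join_con_storfs <- function(ur, params = storf_params()) {
  ur <- .as_ur(ur)
  max_join <- params$max_stops_spanned - 1L
  if (max_join < 2L) return(.empty_storfs())
  .storf_candidates(ur$id, ur$sequence, params,
                    span_sizes = 2:max_join, apply_length_filter = TRUE)
}

#' Filter overlapping StORF candidates (descending-length rule)
#'
#' Candidates from one UR are sorted by length descending (ties broken by
#' smaller `ur_start`, then smaller frame) and accepted greedily: a
#' candidate is retained iff its overlap with every already-retained
#' candidate is at most `max_overlap` nt.  Overlap is measured on forward
#' UR spans regardless of strand or frame, so nested candidates are always
#' removed.
#'
#' @param candidates Candidate data frame for a single UR.
#' @param params A [storf_params()] object.
#' @return The retained subset, in acceptance (length-descending) order.
#' @export
filter_storfs <- function(candidates, params = storf_params()) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return(.empty_storfs())
  }
  ord <- order(-candidates$length, candidates$ur_start, candidates$frame)
  cand <- candidates[ord, , drop = FALSE]
  acc_s <- integer(0)
  acc_e <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$ur_start[i]
    e <- cand$ur_end[i]
    ov <- pmax(0L, pmin(acc_e, e) - pmax(acc_s, s))
    if (!length(ov) || max(ov) <= params$max_overlap) {
      keep[i] <- TRUE
      acc_s <- c(acc_s, s)
      acc_e <- c(acc_e, e)
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Translate a StORF under the bacterial genetic code
#'
#' Translates the interval between the delimiting stop codons with codon
#' table 11 and no start-codon special-casing: alternative starts such as
#' GTG or TTG are reported as the amino acid of the codon table (V, L),
#' never rewritten to methionine, because the true initiation site is
#' unknown.  Codons containing ambiguity codes translate to `X`; internal
#' stops (Con-StORFs) render as `*`.
#'
#' @param dna StORF DNA including both delimiting stop codons; length must
#'   be divisible by 3.
#' @param params A [storf_params()] object (unused by the genetic code but
#'   kept for interface symmetry).
#' @return Amino-acid string of length `nchar(dna)/3 - 2` minus nothing
#'   (internal stops appear as `*`).
#' @export
translate_storf <- function(dna, params = storf_params()) {
  n <- nchar(dna)
  if (n %% 3L != 0L) {
    stop("StORF length not divisible by 3: ", n, call. = FALSE)
  }
  if (n < 6L) {
    stop("StORF shorter than two codons: ", n, call. = FALSE)
  }
  core <- substr(dna, 4L, n - 3L)
  if (!nzchar(core)) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(core),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE,
    if.fuzzy.codon = "X"))
}

#' Map a StORF's UR span onto genome coordinates
#'
#' @param storf Data frame of StORF records with `ur_start`, `ur_end`,
#'   `frame` columns (0-based half-open UR spans).
#' @param ur The one-row UR record the StORFs came from.
#' @return `storf` with `genome_start`, `genome_end` (1-based inclusive on
#'   the genome forward strand) and `strand` columns set (`-` iff frame is
#'   4-6).
#' @export
to_genome_coordinates <- function(storf, ur) {
  ur <- .as_ur(ur)
  n <- nchar(ur$sequence)
  if (nrow(storf)) {
    if (any(storf$ur_start < 0L) || any(storf$ur_end > n)) {
      stop("StORF span exceeds UR bounds", call. = FALSE)
    }
  }
  storf$genome_start <- ur$ext_start + storf$ur_start
  storf$genome_end <- ur$ext_start + storf$ur_end - 1L
  storf$strand <- ifelse(storf$frame > 3L, "-", "+")
  storf
}

#' Find, filter and annotate StORFs across a set of unannotated regions
#'
#' Runs the per-UR pipeline: enumerate plain StORFs (and Con-StORFs when
#' enabled) without a length pre-filter, apply the min/max length filter to
#' the pooled candidates, apply the descending-length overlap filter, then
#' translate and map the retained set to genome coordinates.  Filtering is
#' strictly per-UR; StORFs of different URs are never compared.
#'
#' @param urs UR data frame from [extract_unannotated_regions()].
#' @param params A [storf_params()] object.
#' @return Data frame of retained StORFs with ids
#'   `"<ur_id>_StORF_<n>"` (numbered by position within the UR), contig,
#'   frame, strand, UR-relative and genome spans, `dna` and `protein`.
#' @export
find_storfs <- function(urs, params = storf_params()) {
  out <- list()
  for (i in seq_len(nrow(urs))) {
    ur <- urs[i, , drop = FALSE]
    cand <- enumerate_storfs(ur, params, apply_length_filter = FALSE)
    if (params$report_con_storfs) {
      cand <- rbind(cand, join_con_storfs(ur, params))
    }
    cand <- cand[cand$length >= params$min_storf_len &
                 cand$length <= params$max_storf_len, , drop = FALSE]
    kept <- filter_storfs(cand, params)
    if (!nrow(kept)) next
    kept <- kept[order(kept$ur_start, kept$frame), , drop = FALSE]
    kept$id <- paste0(ur$id, "_StORF_", seq_len(nrow(kept)))
    kept$contig <- ur$contig
    kept <- to_genome_coordinates(kept, ur)
    kept$protein <- vapply(kept$dna, translate_storf, character(1),
                           params = params, USE.NAMES = FALSE)
    out[[length(out) + 1L]] <- kept
  }
  if (!length(out)) {
    res <- .empty_storfs()
    res$id <- character(0)
    res$contig <- character(0)
    res$genome_start <- integer(0)
    res$genome_end <- integer(0)
    res$protein <- character(0)
    return(res)
  }
  res <- do.call(rbind, out)
  cols <- c("id", "ur_id", "contig", "frame", "strand", "ur_start", "ur_end",
            "genome_start", "genome_end", "length", "storf_type",
            "stops_spanned", "dna", "protein")
  res <- res[, cols]
  rownames(res) <- NULL
  res
}

#' Write StORFs as GFF3 and/or FASTA
#'
#' @param storfs StORF data frame from [find_storfs()].
#' @param gff_path,fasta_path Output paths; `NULL` to skip.
#' @param what `"aa"` (default) or `"nt"`: which sequence goes to FASTA.
#' @return Invisibly, the list of paths written.
#' @export
write_storfs <- function(storfs, gff_path = NULL, fasta_path = NULL,
                         what = c("aa", "nt")) {
  what <- match.arg(what)
  if (!is.null(gff_path)) {
    feats <- data.frame(
      contig = storfs$contig, source = "StORF-Reporter", type = "ORF",
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
      stringsAsFactors = FALSE)
    write_gff(feats, gff_path)
  }
  if (!is.null(fasta_path)) {
    seqs <- if (what == "aa") storfs$protein else storfs$dna
    names(seqs) <- paste0(storfs$id, "|", storfs$contig, ":",
                          storfs$genome_start, "-", storfs$genome_end,
                          "(", storfs$strand, ")|frame=", storfs$frame)
    write_fasta(seqs, fasta_path)
  }
  invisible(list(gff = gff_path, fasta = fasta_path))
}
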