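# Synthetic genomes with planted stop-delimited genes, recovery scoring,
# and CD-HIT cluster-file fixtures with known classifications.
#
# Construction guarantees (documented in the methods vignette):
#  * intergenic filler carries a 15-nt "stop cassette" at both ends and at
#    least every 45 nt.  The cassette TAATTAATTAATTAA contains a stop codon
#    in all six frames, so no unannotated stretch can harbour a spurious
#    stop-free run anywhere near the default 100 nt StORF minimum;
#  * hidden (planted) genes are stop-delimited and internally stop-free in
#    their own frame, while a recurring codon-aligned salt motif puts stop
#    codons into the other five frames, so the only StORF of qualifying
#    length over a planted gene is the gene itself.

# Stops in all six frames (offsets 0,4,8 forward; 3,7,11 reverse).
.stop_cassette <- "TAATTAATTAATTAA"
# Five codons, stop-free in frame 0, with stops in the remaining five
# frames: TTA ATA ATT AAC TAC.
.salt_codons <- c("TTA", "ATA", "ATT", "AAC", "TAC")

.canonical_stops <- c("TAA", "TAG", "TGA")

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

.all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

# Sample n codons outside the canonical stop set, weighted towards the
# requested GC content.
.random_codons <- function(n, gc) {
  if (n == 0L) return(character(0))
  codons <- setdiff(.all_codons(), .canonical_stops)
  p <- .base_probs(gc)
  w <- vapply(strsplit(codons, ""), function(x) prod(p[x]), numeric(1))
  sample(codons, n, replace = TRUE, prob = w)
}

# Intergenic filler: GC-weighted random bases overwritten with stop
# cassettes at the start, the end, and at least every 45 nt in between.
.filler <- function(len, gc) {
  if (len <= 0L) return("")
  chars <- sample(names(.base_probs(gc)), len, replace = TRUE,
                  prob = .base_probs(gc))
  cas <- strsplit(.stop_cassette, "")[[1]]
  w <- length(cas)
  if (len >= w) {
    starts <- unique(c(seq(1L, len - w + 1L, by = 45L), len - w + 1L))
    for (s in starts) {
      chars[s:(s + w - 1L)] <- cas
    }
  }
  paste(chars, collapse = "")
}

# A stop-delimited, internally stop-free (frame 0) gene whose off-frames
# are salted with stops; total length is a multiple of 3 including both
# delimiting stops.
.hidden_gene_seq <- function(len, gc) {
  stopifnot(len %% 3L == 0L, len >= 36L)
  m <- len / 3L - 2L
  codons <- character(0)
  while (length(codons) < m) {
    codons <- c(codons, .salt_codons, .random_codons(5L, gc))
  }
  paste0("TAA", paste(codons[seq_len(m)], collapse = ""), "TAG")
}

# An ORF-like annotated gene: ATG + stop-free body + stop.
.annotated_gene_seq <- function(len, gc) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  body <- .random_codons(len / 3L - 2L, gc)
  paste0("ATG", paste(body, collapse = ""),
         sample(.canonical_stops, 1L))
}

#' Specification for a synthetic annotated genome
#'
#' @param n_contigs Number of contigs.
#' @param contig_lengths Optional integer vector of target contig lengths
#'   (nt); when given, contigs are padded with intergenic filler to the
#'   target and it is an error if the placed genes do not fit.  `NULL`
#'   (default) sizes each contig by its content.
#' @param n_annotated_genes Genes written to the annotation (type
#'   `"gene"`).
#' @param n_hidden_genes Stop-delimited genes planted inside unannotated
#'   gaps and absent from the annotation.
#' @param hidden_gene_length_range Length range (nt) of hidden genes;
#'   both ends multiples of 3, minimum 120 by default so every planted
#'   gene clears the default StORF length floor.
#' @param annotated_gene_length_range Length range (nt) of annotated
#'   genes (multiples of 3 are drawn within it).
#' @param gc_content Target GC fraction of random sequence.
#' @param intergenic_gap_range Length range (nt) of plain intergenic gaps.
#' @param hidden_gap_pad_range Range (nt) of the filler pad placed on each
#'   side of a hidden gene inside its gap.
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated `synthetic_genome_spec` object.
#' @export
synthetic_genome_spec <- function(n_contigs = 1, contig_lengths = NULL,
                                  n_annotated_genes = 30,
                                  n_hidden_genes = 10,
                                  hidden_gene_length_range = c(120, 300),
                                  annotated_gene_length_range = c(300, 900),
                                  gc_content = 0.5,
                                  intergenic_gap_range = c(60, 240),
                                  hidden_gap_pad_range = c(50, 80),
                                  seed = 1) {
  stopifnot(n_contigs >= 1, n_annotated_genes >= n_contigs,
            n_hidden_genes >= 0, gc_content > 0, gc_content < 1,
            length(hidden_gene_length_range) == 2,
            all(hidden_gene_length_range %% 3 == 0),
            hidden_gene_length_range[1] >= 120,
            diff(hidden_gene_length_range) >= 0,
            annotated_gene_length_range[1] >= 90,
            diff(annotated_gene_length_range) >= 0,
            intergenic_gap_range[1] >= 30,
            diff(intergenic_gap_range) >= 0,
            hidden_gap_pad_range[1] >= 50,
            diff(hidden_gap_pad_range) >= 0)
  if (!is.null(contig_lengths)) {
    stopifnot(length(contig_lengths) == n_contigs, all(contig_lengths > 0))
  }
  structure(list(n_contigs = as.integer(n_contigs),
                 contig_lengths = contig_lengths,
                 n_annotated_genes = as.integer(n_annotated_genes),
                 n_hidden_genes = as.integer(n_hidden_genes),
                 hidden_gene_length_range = as.integer(hidden_gene_length_range),
                 annotated_gene_length_range = as.integer(annotated_gene_length_range),
                 gc_content = gc_content,
                 intergenic_gap_range = as.integer(intergenic_gap_range),
                 hidden_gap_pad_range = as.integer(hidden_gap_pad_range),
                 seed = as.integer(seed)),
            class = "synthetic_genome_spec")
}

.sample_mult3 <- function(range) {
  lo <- ceiling(range[1] / 3L) * 3L
  hi <- floor(range[2] / 3L) * 3L
  3L * sample(seq(lo / 3L, hi / 3L), 1L)
}

.sample_len <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1L)
}

#' Generate a synthetic annotated genome with planted hidden genes
#'
#' Builds contigs as alternating intergenic filler and annotated genes;
#' hidden genes are written into a subset of the gaps, flanked by filler
#' pads, and never appear in the annotation.  Output is deterministic for
#' a given spec (all randomness is drawn from `spec$seed`).
#'
#' @param spec A [synthetic_genome_spec()].
#' @return List with `contigs` (named character vector), `features` (GFF
#'   data frame of the annotated genes only) and `truth` (one row per
#'   hidden gene: contig, 1-based span, strand, length and the gene
#'   sequence read 5'→3' on its own strand).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  .with_seed(spec$seed, {
    gc <- spec$gc_content
    genes_per_contig <- table(factor(
      rep_len(seq_len(spec$n_contigs), spec$n_annotated_genes),
      levels = seq_len(spec$n_contigs)))
    hidden_per_contig <- table(factor(
      rep_len(seq_len(spec$n_contigs), spec$n_hidden_genes)[
        seq_len(spec$n_hidden_genes)],
      levels = seq_len(spec$n_contigs)))
    bad <- which(hidden_per_contig > genes_per_contig + 1L)
    if (length(bad)) {
      stop("infeasible spec: contig ", bad[1], " would need ",
           hidden_per_contig[bad[1]], " hidden genes but has only ",
           genes_per_contig[bad[1]] + 1L, " gaps", call. = FALSE)
    }
    contigs <- character(spec$n_contigs)
    names(contigs) <- sprintf("contig%02d", seq_len(spec$n_contigs))
    feats <- list()
    truth <- list()
    hidden_strand_flip <- TRUE
    for (ci in seq_len(spec$n_contigs)) {
      cid <- names(contigs)[ci]
      ng <- as.integer(genes_per_contig[ci])
      nh <- as.integer(hidden_per_contig[ci])
      n_slots <- ng + 1L
      hidden_slots <- if (nh > 0L) sample(seq_len(n_slots), nh) else integer(0)

      pieces <- character(0)
      pos <- 0L  # length so far
      add <- function(s) {
        pieces[[length(pieces) + 1L]] <<- s
        pos <<- pos + nchar(s)
      }
      for (slot in seq_len(n_slots)) {
        if (slot %in% hidden_slots) {
          add(.filler(.sample_len(spec$hidden_gap_pad_range), gc))
          hlen <- .sample_mult3(spec$hidden_gene_length_range)
          hseq <- .hidden_gene_seq(hlen, gc)
          strand <- if (hidden_strand_flip) "+" else "-"
          hidden_strand_flip <- !hidden_strand_flip
          add(if (strand == "+") hseq else .revcomp_chr(hseq))
          truth[[length(truth) + 1L]] <- data.frame(
            contig = cid, start = pos - hlen + 1L, end = pos,
            strand = strand, length = hlen, dna = hseq,
            stringsAsFactors = FALSE)
          add(.filler(.sample_len(spec$hidden_gap_pad_range), gc))
        } else {
          add(.filler(.sample_len(spec$intergenic_gap_range), gc))
        }
        if (slot <= ng) {
          glen <- .sample_mult3(spec$annotated_gene_length_range)
          gseq <- .annotated_gene_seq(glen, gc)
          gstrand <- sample(c("+", "-"), 1L)
          add(if (gstrand == "+") gseq else .revcomp_chr(gseq))
          feats[[length(feats) + 1L]] <- data.frame(
            contig = cid, source = "synthetic", type = "gene",
            start = pos - glen + 1L, end = pos, score = ".",
            strand = gstrand, phase = ".",
            attributes = gff_attributes(
              ID = sprintf("gene-%s-%03d", cid, slot)),
            stringsAsFactors = FALSE)
        }
      }
      if (!is.null(spec$contig_lengths)) {
        target <- spec$contig_lengths[ci]
        if (pos > target) {
          stop("infeasible spec: contig ", cid, " content (", pos,
               " nt) exceeds its target length (", target, " nt)",
               call. = FALSE)
        }
        if (pos < target) add(.filler(target - pos, gc))
      }
      contigs[[ci]] <- paste(pieces, collapse = "")
    }
    features <- do.call(rbind, feats)
    rownames(features) <- NULL
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(contig = character(), start = integer(), end = integer(),
                 strand = character(), length = integer(), dna = character(),
                 stringsAsFactors = FALSE)
    rownames(truth_df) <- NULL
    list(contigs = contigs, features = features, truth = truth_df)
  })
}

# Genome-forward frame compatibility: a StORF covers a gene in frame iff
# it lies on the same strand and its codon grid lines up with the gene's.
.in_frame <- function(gene_start, gene_end, gene_strand,
                      s_start, s_end, s_strand) {
  if (gene_strand != s_strand) return(FALSE)
  if (gene_strand == "+") {
    (s_start %% 3L) == (gene_start %% 3L)
  } else {
    (s_end %% 3L) == (gene_end %% 3L)
  }
}

#' Score recovery of planted genes by retained StORFs
#'
#' A planted gene counts as detected iff some retained StORF overlaps it
#' on the same strand and reading frame by at least `min_coverage` of the
#' gene's length (default 75%, the standard in-frame detection criterion
#' for CDS prediction benchmarking).
#'
#' @param truth Truth table from [generate_genome()].
#' @param storfs Retained StORF data frame from [find_storfs()].
#' @param min_coverage Minimum in-frame coverage fraction (default 0.75).
#' @return List with `genes` (truth plus `detected` flag and best in-frame
#'   `coverage`) and `summary` (`n_truth`, `n_detected`, `n_missed`,
#'   `n_surplus` — retained StORFs overlapping no planted gene at all —
#'   and `recovery`, the detected fraction).
#' @export
evaluate_recovery <- function(truth, storfs, min_coverage = 0.75) {
  n <- nrow(truth)
  detected <- logical(n)
  coverage <- numeric(n)
  overlapped_storf <- logical(nrow(storfs))
  for (i in seq_len(n)) {
    g <- truth[i, ]
    same_contig <- storfs$contig == g$contig
    for (j in which(same_contig)) {
      ov <- min(g$end, storfs$genome_end[j]) -
        max(g$start, storfs$genome_start[j]) + 1L
      if (ov <= 0L) next
      overlapped_storf[j] <- TRUE
      if (.in_frame(g$start, g$end, g$strand,
                    storfs$genome_start[j], storfs$genome_end[j],
                    storfs$strand[j])) {
        cov <- ov / g$length
        coverage[i] <- max(coverage[i], cov)
        if (cov >= min_coverage) detected[i] <- TRUE
      }
    }
  }
  genes <- truth
  genes$detected <- detected
  genes$coverage <- coverage
  list(genes = genes,
       summary = list(n_truth = n,
                      n_detected = sum(detected),
                      n_missed = sum(!detected),
                      n_surplus = sum(!overlapped_storf),
                      recovery = if (n) sum(detected) / n else NA_real_))
}

#' Generate a matched pair of CD-HIT cluster files with known truth
#'
#' Emits syntactically valid `.clstr` text for a two-round clustering:
#' round 1 holds the annotated-protein families (one cluster per
#' sub-family), round 2 holds one cluster per final family, containing the
#' round-1 representatives of its sub-families plus its StORF sequences.
#' The true classification of every family follows from the construction.
#'
#' @param n_genomes Total genomes in the pangenome.
#' @param n_genera Number of genera; genome `i` belongs to genus
#'   `((i-1) %% n_genera) + 1` and is labelled `G<genus>_genome<i>`.
#' @param families List of family specs; each element is a list with
#'   `ens` (a list of integer vectors of genome indices, one per round-1
#'   sub-family; may be empty) and `storf` (an integer vector of genome
#'   indices contributing StORF sequences; may be empty).  Every family
#'   must have at least one member.
#' @param seed Integer seed for the cosmetic fields (lengths, identities).
#' @return List with `round1` and `round2` (character vectors of `.clstr`
#'   lines), `truth` (one row per family: expected `cluster_type`,
#'   `prevalence_all`, `fraction`, `prevalence_storf_only`, `n_genomes`,
#'   `n_genera`, `n_members`) and `genomes` (the genome/genus table).
#' @export
generate_clstr_fixture <- function(n_genomes, n_genera, families, seed = 1) {
  stopifnot(n_genomes >= 1, n_genera >= 1, n_genera <= n_genomes,
            is.list(families), length(families) >= 1)
  genus_of <- function(i) sprintf("G%02d", ((i - 1L) %% n_genera) + 1L)
  genome_of <- function(i) sprintf("%s_genome%03d", genus_of(i), i)
  band_of <- function(frac) {
    if (frac >= 0.99) "core" else if (frac >= 0.95) "soft-core"
    else if (frac >= 0.15) "accessory" else "rare"
  }
  .with_seed(seed, {
    r1 <- character(0)
    r2 <- character(0)
    truth <- list()
    r1_cluster <- -1L
    ens_seq <- 0L
    storf_seq <- 0L
    for (fi in seq_along(families)) {
      fam <- families[[fi]]
      ens <- if (is.null(fam$ens)) list() else fam$ens
      storf <- if (is.null(fam$storf)) integer(0) else fam$storf
      ens <- ens[lengths(ens) > 0L]
      all_idx <- c(unlist(ens, use.names = FALSE), storf)
      if (!length(all_idx)) {
        stop("family ", fi, " has no members", call. = FALSE)
      }
      if (any(all_idx < 1L | all_idx > n_genomes)) {
        stop("family ", fi, ": genome index outside 1..", n_genomes,
             call. = FALSE)
      }
      rep_ids <- character(0)
      for (sub in ens) {
        r1_cluster <- r1_cluster + 1L
        r1 <- c(r1, sprintf(">Cluster %d", r1_cluster))
        ids <- vapply(sub, function(g) {
          ens_seq <<- ens_seq + 1L
          sprintf("%s|ENSP%05d", genome_of(g), ens_seq)
        }, character(1))
        rep_ids <- c(rep_ids, ids[1])
        lens <- c(200L + sample(0:80, 1L),
                  sample(120:199, length(ids) - 1L, replace = TRUE))
        for (k in seq_along(ids)) {
          tail <- if (k == 1L) "*" else
            sprintf("at %.2f%%", stats::runif(1, 90, 100))
          r1 <- c(r1, sprintf("%d\t%daa, >%s... %s", k - 1L, lens[k],
                              ids[k], tail))
        }
      }
      storf_ids <- vapply(storf, function(g) {
        storf_seq <<- storf_seq + 1L
        sprintf("%s|contig01_UR_%d_StORF_1", genome_of(g), storf_seq)
      }, character(1))
      members2 <- c(rep_ids, storf_ids)
      r2 <- c(r2, sprintf(">Cluster %d", fi - 1L))
      lens2 <- c(300L, sample(120:299, length(members2) - 1L,
                              replace = TRUE))
      for (k in seq_along(members2)) {
        tail <- if (k == 1L) "*" else
          sprintf("at %.2f%%", stats::runif(1, 90, 100))
        r2 <- c(r2, sprintf("%d\t%daa, >%s... %s", k - 1L, lens2[k],
                            members2[k], tail))
      }
      fam_genomes <- unique(vapply(all_idx, genome_of, character(1)))
      fam_genera <- unique(vapply(all_idx, genus_of, character(1)))
      has_storf <- length(storf) > 0L
      type <- if (!length(ens)) "StORF-Only"
        else if (!has_storf) "Ensembl-Only"
        else if (length(ens) >= 2L) "StORF-Combined-Ensembl"
        else "Ensembl-StORF"
      frac <- length(fam_genomes) / n_genomes
      storf_genomes <- unique(vapply(storf, genome_of, character(1)))
      truth[[fi]] <- data.frame(
        cluster_id = fi - 1L,
        cluster_type = type,
        prevalence_all = band_of(frac),
        fraction = frac,
        prevalence_storf_only = if (has_storf) {
          band_of(length(storf_genomes) / n_genomes)
        } else NA_character_,
        n_genomes = length(fam_genomes),
        n_genera = length(fam_genera),
        n_members = length(all_idx),
        stringsAsFactors = FALSE)
    }
    truth_df <- do.call(rbind, truth)
    rownames(truth_df) <- NULL
    idx <- seq_len(n_genomes)
    list(round1 = r1, round2 = r2, truth = truth_df,
         genomes = data.frame(genome = vapply(idx, genome_of, character(1)),
                              genus = vapply(idx, genus_of, character(1)),
                              stringsAsFactors = FALSE))
  })
}
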