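# Pangenome layer: parse CD-HIT `.clstr` files, label sequence origins,
# classify gene-family clusters by type and prevalence, and tally their
# spread across genera.
#
# The workflow mirrors a two-round clustering: round 1 clusters the
# annotated proteins only; round 2 clusters the round-1 representatives
# together with the StORF proteins.  Round-2 members that are round-1
# representatives are expanded back into their full round-1 memberships
# before prevalence is computed.

#' Parse a CD-HIT cluster file
#'
#' Accepts a path or the file's lines.  The dialect is `>Cluster N`
#' headers followed by member lines of the form
#' `i<TAB><len>aa, ><id>... at <pct>%` with the representative marked
#' `... *`.  Ids are truncated at `...` by CD-HIT; truncated prefixes must
#' be unique across the file.
#'
#' @param x Path to a `.clstr` file, or a character vector of its lines.
#' @return Data frame with columns `cluster_id` (integer, as numbered in
#'   the file), `seq_id`, `length_aa`, `is_rep` and `identity` (percent;
#'   `NA` for representatives).
#' @export
parse_cdhit_clstr <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[nzchar(lines)]
  rows <- vector("list", length(lines))
  cluster_id <- NA_integer_
  n <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">Cluster")) {
      cluster_id <- as.integer(sub("^>Cluster\\s+", "", ln))
      if (is.na(cluster_id)) {
        stop(".clstr line ", i, ": malformed cluster header", call. = FALSE)
      }
      next
    }
    if (is.na(cluster_id)) {
      stop(".clstr line ", i, ": member line before any cluster header",
           call. = FALSE)
    }
    m <- regexec("^\\d+\\t(\\d+)(?:aa|nt), >(.*?)(\\.\\.\\.)?\\s+(\\*|at\\s+.*)$",
                 ln)
    g <- regmatches(ln, m)[[1]]
    if (!length(g)) {
      stop(".clstr line ", i, ": unparseable member line: ", ln,
           call. = FALSE)
    }
    is_rep <- identical(g[5], "*")
    identity <- NA_real_
    if (!is_rep) {
      pm <- regmatches(g[5], regexec("([0-9.]+)%", g[5]))[[1]]
      if (length(pm)) identity <- as.numeric(pm[2])
    }
    n <- n + 1L
    rows[[n]] <- data.frame(cluster_id = cluster_id, seq_id = g[3],
                            length_aa = as.integer(g[2]), is_rep = is_rep,
                            identity = identity, stringsAsFactors = FALSE)
  }
  if (!n) {
    stop("no cluster members found", call. = FALSE)
  }
  out <- do.call(rbind, rows[seq_len(n)])
  reps_per_cluster <- tapply(out$is_rep, out$cluster_id, sum)
  if (any(reps_per_cluster == 0)) {
    stop("cluster(s) without a representative: ",
         paste(names(reps_per_cluster)[reps_per_cluster == 0],
               collapse = ", "), call. = FALSE)
  }
  if (any(reps_per_cluster > 1)) {
    stop("cluster(s) with duplicate representatives: ",
         paste(names(reps_per_cluster)[reps_per_cluster > 1],
               collapse = ", "), call. = FALSE)
  }
  dup <- unique(out$seq_id[duplicated(out$seq_id)])
  if (length(dup)) {
    stop("ambiguous (truncated) sequence id prefix(es): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Parse origin labels from sequence ids
#'
#' The combined-FASTA convention is `genome|protein`; the genome label is
#' the prefix before the first `|` and the genus is its first
#' underscore-delimited token (overridable with a genome-to-genus map).
#' A sequence is a StORF iff its id contains the tag `StORF`.
#'
#' @param ids Character vector of sequence ids.
#' @param genus_map Optional named character vector mapping genome labels
#'   to genus names.
#' @return Data frame with `raw_id`, `genome` (`NA` when no `|` prefix is
#'   present), `genus` and `is_storf`.
#' @export
sequence_labels <- function(ids, genus_map = NULL) {
  has_bar <- grepl("|", ids, fixed = TRUE)
  genome <- ifelse(has_bar, sub("\\|.*$", "", ids), NA_character_)
  genus <- ifelse(is.na(genome), NA_character_,
                  sub("_.*$", "", genome))
  if (!is.null(genus_map)) {
    hit <- !is.na(genome) & genome %in% names(genus_map)
    genus[hit] <- unname(genus_map[genome[hit]])
  }
  data.frame(raw_id = ids, genome = genome, genus = genus,
             is_storf = grepl("StORF", ids, fixed = TRUE),
             stringsAsFactors = FALSE)
}

#' Classify a cluster by sequence origin
#'
#' @param member_ids Raw sequence ids of one round-2 cluster.
#' @param first_round_rep_ids Representative ids of the first
#'   (annotated-proteins-only) clustering round.
#' @return One of `"StORF-Only"` (every member is a StORF),
#'   `"Ensembl-Only"` (no member is), `"StORF-Combined-Ensembl"` (StORFs
#'   bridged two or more formerly distinct annotated families, i.e. the
#'   cluster holds at least two round-1 representatives) or
#'   `"Ensembl-StORF"`.
#' @export
classify_cluster_type <- function(member_ids, first_round_rep_ids) {
  if (!length(member_ids)) {
    stop("empty cluster", call. = FALSE)
  }
  is_storf <- grepl("StORF", member_ids, fixed = TRUE)
  if (all(is_storf)) return("StORF-Only")
  if (!any(is_storf)) return("Ensembl-Only")
  if (sum(member_ids %in% first_round_rep_ids) >= 2L) {
    return("StORF-Combined-Ensembl")
  }
  "Ensembl-StORF"
}

#' Classify a cluster's pangenome prevalence
#'
#' The prevalence fraction is the number of unique genomes contributing a
#' counted member divided by the total genome count (duplicates from one
#' genome count once).  Bands: core at `>= 99%`, soft-core at `>= 95%` and
#' `< 99%`, accessory at `>= 15%` and `< 95%`, and `rare` below that.
#'
#' @param genomes Genome labels of the counted members (one entry per
#'   member; `NA`s are dropped).
#' @param total_genomes Total number of genomes in the pangenome.
#' @param thresholds Band edges as fractions, in the order core,
#'   soft-core, accessory.
#' @return List with `category`, `fraction` and `n_genomes`.
#' @export
classify_prevalence <- function(genomes, total_genomes,
                                thresholds = c(core = 0.99,
                                               soft_core = 0.95,
                                               accessory = 0.15)) {
  stopifnot(total_genomes >= 1, length(thresholds) == 3,
            !is.unsorted(rev(thresholds)))
  ng <- length(unique(genomes[!is.na(genomes)]))
  frac <- ng / total_genomes
  category <- if (frac >= thresholds[[1]]) "core"
    else if (frac >= thresholds[[2]]) "soft-core"
    else if (frac >= thresholds[[3]]) "accessory"
    else "rare"
  list(category = category, fraction = frac, n_genomes = ng)
}

.prevalence_bands <- c("core", "soft-core", "accessory", "rare")
.genera_bins <- c("1", "2", "3", "4", "5", "6", ">6")

.bin_genera <- function(n) {
  ifelse(n > 6, ">6", as.character(n))
}

#' Tally cluster counts by type and genera spread
#'
#' Counts each classified cluster once in its type row and its
#' number-of-genera bin (1-6 and `>6`).  The `StORF` row re-counts the
#' clusters that contain both annotated and StORF sequences by the genera
#' of their StORF members only.  StORF-Only clusters with a single
#' sequence are excluded.
#'
#' @param clusters Per-cluster data frame from [build_pangenome()].
#' @return Data frame with a `cluster_type` column and one column per
#'   genera bin.
#' @export
genera_spread <- function(clusters) {
  types <- c("Ensembl-Only", "Ensembl-StORF", "StORF-Combined-Ensembl",
             "StORF", "StORF-Only")
  tab <- matrix(0L, nrow = length(types), ncol = length(.genera_bins),
                dimnames = list(types, .genera_bins))
  for (i in seq_len(nrow(clusters))) {
    ty <- clusters$cluster_type[i]
    if (ty == "StORF-Only" && clusters$n_members[i] == 1L) next
    if (clusters$n_genera[i] >= 1L) {
      tab[ty, .bin_genera(clusters$n_genera[i])] <-
        tab[ty, .bin_genera(clusters$n_genera[i])] + 1L
    }
    if (ty %in% c("Ensembl-StORF", "StORF-Combined-Ensembl") &&
        !is.na(clusters$n_genera_storf[i]) &&
        clusters$n_genera_storf[i] >= 1L) {
      tab["StORF", .bin_genera(clusters$n_genera_storf[i])] <-
        tab["StORF", .bin_genera(clusters$n_genera_storf[i])] + 1L
    }
  }
  out <- data.frame(cluster_type = types, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(tab, stringsAsFactors = FALSE))
  names(out) <- c("cluster_type", .genera_bins)
  rownames(out) <- NULL
  out
}

.as_clstr <- function(x) {
  if (is.data.frame(x)) return(x)
  if (!length(x)) {
    # a legitimate empty round (e.g. no annotated proteins at all)
    return(data.frame(cluster_id = integer(), seq_id = character(),
                      length_aa = integer(), is_rep = logical(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  parse_cdhit_clstr(x)
}

#' Build a classified pangenome from two CD-HIT rounds
#'
#' Round 1 is the clustering of the annotated proteins only; round 2
#' clusters the round-1 representatives together with the StORF proteins.
#' Every round-2 member that is a round-1 representative is expanded into
#' its round-1 member list, reconstructing full family membership; each
#' family is then classified by origin type and by prevalence under both
#' counting modes (all members, and StORF members only).
#'
#' @param round1,round2 Parsed cluster data frames (see
#'   [parse_cdhit_clstr()]), or paths/lines to parse.
#' @param total_genomes Total number of genomes in the pangenome.
#' @param genus_map Optional genome-to-genus map (see
#'   [sequence_labels()]).
#' @param thresholds Prevalence band edges (see [classify_prevalence()]).
#' @return List with `clusters` (one row per round-2 family: type, both
#'   prevalence classifications, genome/genera counts, member counts),
#'   `summary` (counts of families per type and prevalence band; the
#'   `StORF` row re-counts mixed families by their StORF members only) and
#'   `genera` (the [genera_spread()] table).
#' @export
build_pangenome <- function(round1, round2, total_genomes,
                            genus_map = NULL,
                            thresholds = c(core = 0.99, soft_core = 0.95,
                                           accessory = 0.15)) {
  r1 <- .as_clstr(round1)
  r2 <- .as_clstr(round2)
  reps1 <- r1$seq_id[r1$is_rep]
  members1 <- split(r1$seq_id, r1$cluster_id)
  rep_cluster <- r1$cluster_id[r1$is_rep]
  names(rep_cluster) <- reps1

  cluster_ids <- unique(r2$cluster_id)
  rows <- vector("list", length(cluster_ids))
  for (j in seq_along(cluster_ids)) {
    cid <- cluster_ids[[j]]
    ids <- r2$seq_id[r2$cluster_id == cid]
    is_storf <- grepl("StORF", ids, fixed = TRUE)
    stray <- ids[!is_storf & !(ids %in% reps1)]
    if (length(stray)) {
      stop("round-2 member is neither a StORF nor a round-1 ",
           "representative: ", paste(stray, collapse = ", "), call. = FALSE)
    }
    expanded <- c(ids[is_storf],
                  unlist(members1[as.character(rep_cluster[ids[!is_storf]])],
                         use.names = FALSE))
    lab <- sequence_labels(expanded, genus_map)
    type <- classify_cluster_type(ids, reps1)
    prev_all <- classify_prevalence(lab$genome, total_genomes, thresholds)
    storf_lab <- lab[lab$is_storf, , drop = FALSE]
    has_storf <- nrow(storf_lab) > 0L
    prev_storf <- if (has_storf) {
      classify_prevalence(storf_lab$genome, total_genomes, thresholds)
    } else {
      list(category = NA_character_, fraction = NA_real_, n_genomes = NA_integer_)
    }
    rows[[j]] <- data.frame(
      cluster_id = cid,
      cluster_type = type,
      prevalence_all = prev_all$category,
      fraction = prev_all$fraction,
      n_genomes = prev_all$n_genomes,
      prevalence_storf_only = prev_storf$category,
      fraction_storf_only = prev_storf$fraction,
      n_genomes_storf = prev_storf$n_genomes,
      n_members = length(expanded),
      n_storf_members = sum(lab$is_storf),
      n_genera = length(unique(lab$genus[!is.na(lab$genus)])),
      n_genera_storf = if (has_storf) {
        length(unique(storf_lab$genus[!is.na(storf_lab$genus)]))
      } else NA_integer_,
      stringsAsFactors = FALSE)
  }
  clusters <- do.call(rbind, rows)
  rownames(clusters) <- NULL

  types <- c("Ensembl-Only", "Ensembl-StORF", "StORF-Combined-Ensembl",
             "StORF", "StORF-Only")
  summ <- matrix(0L, nrow = length(types), ncol = length(.prevalence_bands),
                 dimnames = list(types, .prevalence_bands))
  for (i in seq_len(nrow(clusters))) {
    ty <- clusters$cluster_type[i]
    summ[ty, clusters$prevalence_all[i]] <-
      summ[ty, clusters$prevalence_all[i]] + 1L
    if (ty %in% c("Ensembl-StORF", "StORF-Combined-Ensembl")) {
      summ["StORF", clusters$prevalence_storf_only[i]] <-
        summ["StORF", clusters$prevalence_storf_only[i]] + 1L
    }
  }
  summary_df <- data.frame(cluster_type = types, stringsAsFactors = FALSE)
  summary_df <- cbind(summary_df, as.data.frame(summ, stringsAsFactors = FALSE))
  names(summary_df) <- c("cluster_type", .prevalence_bands)
  rownames(summary_df) <- NULL

  list(clusters = clusters, summary = summary_df,
       genera = genera_spread(clusters))
}
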