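# Independent oracles and fixture builders.  Everything here is written
# against the definitions, not against the package internals: string
# reverse complement via chartr, stop scanning via an explicit sliding
# window, UR extraction via an occupancy array, StORF filtering via an
# independently coded greedy trace.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

make_features <- function(contig, starts, ends, type = "gene",
                          strand = "+") {
  data.frame(contig = contig, source = "test", type = type,
             start = as.integer(starts), end = as.integer(ends),
             score = ".", strand = strand, phase = ".",
             attributes = paste0("ID=f", seq_along(starts)),
             stringsAsFactors = FALSE)
}

# Occupancy-array UR oracle: mark every annotated base, scan runs of
# unannotated bases >= min_gap, extend both ends with clamping, drop
# regions longer than max_len after extension.
oracle_urs <- function(contigs, features, min_gap = 30, extension = 50,
                       max_len = 100000) {
  out <- list()
  for (cid in sort(names(contigs))) {
    L <- nchar(contigs[[cid]])
    occ <- logical(L)
    f <- features[features$contig == cid, , drop = FALSE]
    for (i in seq_len(nrow(f))) occ[f$start[i]:f$end[i]] <- TRUE
    r <- rle(c(occ))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (r$values[j] || r$lengths[j] < min_gap) next
      es <- as.integer(max(1, starts[j] - extension))
      ee <- as.integer(min(L, ends[j] + extension))
      if (ee - es + 1L > max_len) next
      out[[length(out) + 1L]] <- data.frame(
        contig = cid, gap_start = starts[j], gap_end = ends[j],
        ext_start = es, ext_end = ee, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(), gap_start = integer(),
                      gap_end = integer(), ext_start = integer(),
                      ext_end = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Explicit sliding-window stop scan (0-based codon starts).
brute_stops <- function(s, stops = c("TAA", "TAG", "TGA")) {
  n <- nchar(s)
  if (n < 3) return(integer(0))
  hits <- integer(0)
  for (p in 0:(n - 3)) {
    if (substr(s, p + 1, p + 3) %in% stops) hits <- c(hits, p)
  }
  hits
}

# All-pairs StORF oracle: every same-frame stop pair with no same-frame
# stop strictly between defines a candidate; both strands; reverse-strand
# spans mapped back to forward coordinates.
oracle_storfs <- function(seq, stops = c("TAA", "TAG", "TGA"),
                          min_len = 100, max_len = 50000) {
  n <- nchar(seq)
  rows <- list()
  for (dir in c("+", "-")) {
    s <- if (dir == "+") seq else rc(seq)
    hits <- brute_stops(s, stops)
    for (f in 0:2) {
      ps <- hits[hits %% 3 == f]
      if (length(ps) < 2) next
      for (i in seq_along(ps)) {
        for (j in seq_along(ps)) {
          if (j <= i) next
          between <- ps[ps > ps[i] & ps < ps[j]]
          if (length(between)) next
          len <- ps[j] + 3 - ps[i]
          if (len < min_len || len > max_len) next
          if (dir == "+") {
            us <- ps[i]; ue <- ps[j] + 3
          } else {
            us <- n - (ps[j] + 3); ue <- n - ps[i]
          }
          rows[[length(rows) + 1L]] <- data.frame(
            frame = if (dir == "+") f + 1L else f + 4L,
            strand = dir, ur_start = us, ur_end = ue, length = len,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(frame = integer(), strand = character(),
                      ur_start = integer(), ur_end = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$ur_start, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Independently coded greedy descending-length trace.
oracle_filter <- function(cands, max_overlap = 50) {
  cands <- cands[order(-cands$length, cands$ur_start, cands$frame), ,
                 drop = FALSE]
  kept <- list()
  for (i in seq_len(nrow(cands))) {
    ok <- TRUE
    for (k in kept) {
      ov <- min(k$ur_end, cands$ur_end[i]) - max(k$ur_start, cands$ur_start[i])
      if (ov > max_overlap) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1L]] <- cands[i, ]
  }
  if (!length(kept)) return(cands[0, ])
  res <- do.call(rbind, kept)
  rownames(res) <- NULL
  res
}

span_key <- function(df) {
  df <- df[order(df$ur_start, df$frame), , drop = FALSE]
  paste(df$frame, df$strand, df$ur_start, df$ur_end, sep = ":")
}

# Random annotation layout on one contig: k non-degenerate spans, possibly
# overlapping, all within [1, L].
random_layout <- function(seed, L = 2000, k = 6) {
  set.seed(seed)
  starts <- sort(sample(seq_len(L - 100), k))
  ends <- pmin(L, starts + sample(30:300, k, replace = TRUE))
  make_features("c1", starts, ends)
}
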