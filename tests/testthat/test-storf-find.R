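test_that("stop positions are reported per frame and match a window scan", {
  sp <- stop_positions("TAAAAATAG")
  expect_identical(sp[[1]], c(0L, 6L))
  expect_identical(sp[[2]], integer(0))
  expect_identical(sp[[3]], integer(0))
  # restricted stop set (e.g. TGA recoded to tryptophan)
  expect_identical(stop_positions("TGACCC", c("TAA", "TAG")),
                   list(integer(0), integer(0), integer(0)))
  # sliding-window oracle on a random 600-mer
  s <- random_dna(600, seed = 31)
  got <- sort(unlist(stop_positions(s)))
  expect_identical(got, brute_stops(s))
  # codons containing N never match
  expect_identical(unlist(stop_positions("TANTAGNAA")), 3L)
})

single_orf_ur <- function() {
  list(id = "u1", contig = "c1", ext_start = 1L,
       sequence = paste0("TAA", strrep("GCT", 40), "TAG"))
}

test_that("a single stop-delimited frame yields exactly one StORF", {
  s <- enumerate_storfs(single_orf_ur())
  expect_identical(nrow(s), 1L)
  expect_identical(s$frame, 1L)
  expect_identical(c(s$ur_start, s$ur_end), c(0L, 126L))
  expect_identical(s$length, 126L)
  expect_identical(s$stops_spanned, 2L)
  expect_true(startsWith(s$dna, "TAA") && endsWith(s$dna, "TAG"))
  # raising the length floor removes it
  expect_identical(
    nrow(enumerate_storfs(single_orf_ur(), storf_params(min_storf_len = 150))),
    0L)
})

test_that("enumeration matches the all-pairs oracle on random URs", {
  for (seed in 1:60) {
    n <- sample(300:2000, 1)
    seq <- random_dna(n, seed = seed)
    ur <- list(id = "u", contig = "c1", ext_start = 1L, sequence = seq)
    got <- enumerate_storfs(ur)
    want <- oracle_storfs(seq)
    expect_identical(span_key(got), span_key(want),
                     label = paste("seed", seed))
  }
})

test_that("enumeration is reverse-complement symmetric", {
  for (seed in c(5, 19, 77)) {
    seq <- random_dna(1200, seed = seed)
    n <- nchar(seq)
    a <- enumerate_storfs(list(id = "u", ext_start = 1L, sequence = seq))
    b <- enumerate_storfs(list(id = "u", ext_start = 1L, sequence = rc(seq)))
    # mirror b back onto a's coordinates and flip strands
    b$new_start <- n - b$ur_end
    b$new_end <- n - b$ur_start
    b$strand <- ifelse(b$strand == "+", "-", "+")
    key_a <- sort(paste(a$strand, a$ur_start, a$ur_end))
    key_b <- sort(paste(b$strand, b$new_start, b$new_end))
    expect_identical(key_a, key_b)
    expect_setequal(a$dna, b$dna)
  }
})

test_that("consecutive StORFs sharing stops join into Con-StORFs", {
  seq <- paste0("TAA", strrep("A", 99), "TAG", strrep("C", 99), "TGA")
  ur <- list(id = "u1", contig = "c1", ext_start = 1L, sequence = seq)
  plain <- enumerate_storfs(ur)
  expect_identical(nrow(plain), 2L)
  expect_identical(plain$length, c(105L, 105L))
  expect_identical(plain$ur_start, c(0L, 102L))
  con <- join_con_storfs(ur)
  expect_identical(nrow(con), 1L)
  expect_identical(con$length, 207L)  # spans stop 0 through stop at 204
  expect_identical(con$stops_spanned, 3L)
  expect_identical(con$storf_type, "Con-StORF")
  # the all-pairs oracle allowing one internal stop agrees on the span
  hits <- brute_stops(seq)
  expect_identical(hits[hits %% 3 == 0], c(0L, 102L, 204L))
  # a single isolated StORF yields no Con-StORF
  expect_identical(nrow(join_con_storfs(single_orf_ur())), 0L)
  # max_stops_spanned = 2 disables joining entirely
  expect_identical(
    nrow(join_con_storfs(ur, storf_params(max_stops_spanned = 2))), 0L)
  # Con-StORF proteins render the internal stop as '*'
  expect_true(grepl("*", translate_storf(con$dna), fixed = TRUE))
})

fake_cands <- function(starts, ends, frame = 1L) {
  data.frame(ur_id = "u", frame = frame, strand = "+",
             ur_start = as.integer(starts), ur_end = as.integer(ends),
             length = as.integer(ends - starts),
             storf_type = "StORF", stops_spanned = 2L,
             dna = "", stringsAsFactors = FALSE)
}

test_that("the overlap filter keeps 50 nt overlaps and removes beyond", {
  both <- filter_storfs(fake_cands(c(0, 250), c(300, 450)))
  expect_identical(nrow(both), 2L)
  pruned <- filter_storfs(fake_cands(c(0, 240), c(300, 440)))
  expect_identical(nrow(pruned), 1L)
  expect_identical(pruned$ur_start, 0L)  # the longer (300 nt) survives
})

test_that("greedy filtering follows descending length with deterministic ties", {
  # lengths 400 > 300 > 200; overlaps: (A,B)=60, (A,C)=0, (B,C)=55
  cands <- fake_cands(c(0, 340, 585), c(400, 640, 785))
  kept <- filter_storfs(cands)
  expect_identical(kept$ur_start, c(0L, 585L))
  expect_identical(span_key(kept), span_key(oracle_filter(cands)))
  # idempotence
  expect_identical(filter_storfs(kept), kept)
  # pairwise overlap in the retained set never exceeds the cap
  for (seed in c(2, 8, 21)) {
    seq <- random_dna(1800, seed = seed)
    kept <- filter_storfs(enumerate_storfs(
      list(id = "u", ext_start = 1L, sequence = seq)))
    if (nrow(kept) < 2) next
    for (i in seq_len(nrow(kept) - 1)) {
      for (j in (i + 1):nrow(kept)) {
        ov <- min(kept$ur_end[i], kept$ur_end[j]) -
          max(kept$ur_start[i], kept$ur_start[j])
        expect_lte(ov, 50L)
      }
    }
  }
})

test_that("translation uses codon table 11 without start special-casing", {
  expect_identical(translate_storf("TAAATGGCGTAG"), "MA")
  # GTG is reported as valine, never rewritten to methionine
  expect_identical(translate_storf("TAAGTGGCGTAG"), "VA")
  expect_identical(translate_storf("TAAATGNNNGCGTAG"), "MXA")
  expect_error(translate_storf("TAAATGGCGTA"), "divisible by 3")
  # length identity on enumerated StORFs: 3*aa + 3*stops == nt
  seq <- random_dna(1500, seed = 44)
  st <- enumerate_storfs(list(id = "u", ext_start = 1L, sequence = seq))
  for (i in seq_len(nrow(st))) {
    aa <- translate_storf(st$dna[i])
    expect_identical(3L * nchar(aa) + 3L * st$stops_spanned[i], st$length[i])
    expect_false(grepl("*", aa, fixed = TRUE))
  }
})

test_that("genome coordinate mapping offsets UR spans and flags strand", {
  ur <- list(id = "u", contig = "c1", ext_start = 1001L,
             sequence = strrep("A", 500))
  st <- fake_cands(60, 210)  # 150 nt span
  mapped <- to_genome_coordinates(st, ur)
  expect_identical(c(mapped$genome_start, mapped$genome_end), c(1061L, 1210L))
  expect_identical(mapped$strand, "+")
  st4 <- fake_cands(0, 120, frame = 4L)
  mapped4 <- to_genome_coordinates(st4, ur)
  expect_identical(c(mapped4$genome_start, mapped4$genome_end), c(1001L, 1120L))
  expect_identical(mapped4$strand, "-")
  expect_error(to_genome_coordinates(fake_cands(0, 600), ur), "UR bounds")
})

test_that("retained StORFs slice back out of the genome exactly", {
  set.seed(91)
  genome <- c(c1 = random_dna(6000))
  feats <- make_features("c1", c(1, 2500, 5000), c(2000, 4500, 6000))
  urs <- extract_unannotated_regions(genome, feats, ur_params())
  storfs <- find_storfs(urs, storf_params())
  expect_gt(nrow(storfs), 0)
  for (i in seq_len(nrow(storfs))) {
    slice <- substr(genome[["c1"]], storfs$genome_start[i],
                    storfs$genome_end[i])
    if (storfs$strand[i] == "-") slice <- rc(slice)
    expect_identical(slice, storfs$dna[i])
    # delimiting stops are from the configured set, interior is stop-free
    hits <- brute_stops(storfs$dna[i])
    in_frame <- hits[hits %% 3 == 0]
    expect_identical(in_frame, c(0L, storfs$length[i] - 3L))
  }
  # ids carry the load-bearing StORF tag and number within the UR
  expect_true(all(grepl("_StORF_\\d+$", storfs$id)))
  expect_true(all(startsWith(storfs$id, storfs$ur_id)))
})

test_that("the per-UR pipeline equals brute enumeration plus greedy trace", {
  for (seed in 1:40) {
    seq <- random_dna(sample(400:2000, 1), seed = seed + 300)
    ur <- list(id = "u", contig = "c1", ext_start = 1L, sequence = seq)
    got <- filter_storfs(enumerate_storfs(ur))
    want <- oracle_filter(oracle_storfs(seq))
    expect_identical(span_key(got), span_key(want),
                     label = paste("seed", seed))
  }
})
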