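clstr_text <- c(
  ">Cluster 0",
  "0\t214aa, >Eco_g1|ENSP00001... *",
  "1\t210aa, >Eco_g2|ENSP00002... at 97.50%",
  "2\t180aa, >Eco_g3|ENSP00003... at 91.00%",
  ">Cluster 1",
  "0\t120aa, >Sau_g1|ENSP00004... *",
  "1\t119aa, >Sau_g2|ENSP00005... at 95.00%")

test_that("CD-HIT cluster files parse members, reps and identities", {
  cl <- parse_cdhit_clstr(clstr_text)
  expect_identical(nrow(cl), 5L)
  expect_identical(unique(cl$cluster_id), c(0L, 1L))
  expect_identical(sum(cl$is_rep), 2L)
  expect_identical(cl$identity[cl$seq_id == "Eco_g2|ENSP00002"], 97.5)
  expect_true(is.na(cl$identity[cl$is_rep][1]))
  expect_identical(cl$length_aa[1], 214L)
  # a path works too
  tf <- withr::local_tempfile(fileext = ".clstr")
  writeLines(clstr_text, tf)
  expect_identical(parse_cdhit_clstr(tf), cl)
})

test_that("malformed cluster files are rejected", {
  no_rep <- c(">Cluster 0", "0\t100aa, >a|x... at 95.00%")
  expect_error(parse_cdhit_clstr(no_rep), "without a representative")
  two_reps <- c(">Cluster 0", "0\t100aa, >a|x... *", "1\t90aa, >a|y... *")
  expect_error(parse_cdhit_clstr(two_reps), "duplicate representatives")
  collision <- c(">Cluster 0", "0\t100aa, >a|longprefix... *",
                 ">Cluster 1", "0\t90aa, >a|longprefix... *")
  expect_error(parse_cdhit_clstr(collision), "prefix.*a\\|longprefix")
  expect_error(parse_cdhit_clstr(c(">Cluster 0", "garbage")), "unparseable")
})

test_that("sequence labels parse genome, genus and the StORF tag", {
  lab <- sequence_labels(c("Enterobacter_cloacae_ecwsu1.asm23997v1|AEW71445",
                           "Escherichia_coli_x|c1_UR_5_StORF_2",
                           "bare_id_no_bar"))
  expect_identical(lab$genome[1], "Enterobacter_cloacae_ecwsu1.asm23997v1")
  expect_identical(lab$genus[1], "Enterobacter")
  expect_true(lab$is_storf[2])
  expect_false(lab$is_storf[1])
  expect_true(is.na(lab$genome[3]))
  # explicit genus map overrides the underscore convention
  lab2 <- sequence_labels("Eco_x|p1", genus_map = c(Eco_x = "Escherichia"))
  expect_identical(lab2$genus, "Escherichia")
})

test_that("cluster types follow the origin of their members", {
  reps1 <- c("g1|E1", "g2|E2")
  expect_identical(classify_cluster_type(c("g1|E1", "g3|a_StORF_1",
                                           "g4|b_StORF_2"), reps1),
                   "Ensembl-StORF")
  expect_identical(classify_cluster_type(c("g1|E1", "g2|E2", "g3|a_StORF_1"),
                                         reps1),
                   "StORF-Combined-Ensembl")
  expect_identical(classify_cluster_type(c("g1|a_StORF_1", "g2|b_StORF_2"),
                                         reps1),
                   "StORF-Only")
  expect_identical(classify_cluster_type("g1|E1", reps1), "Ensembl-Only")
  expect_error(classify_cluster_type(character(0), reps1), "empty")
})

test_that("prevalence bands split at 99/95/15 percent of unique genomes", {
  g <- function(n) paste0("g", seq_len(n))
  expect_identical(classify_prevalence(g(169), 169)$category, "core")
  p168 <- classify_prevalence(g(168), 169)
  expect_identical(p168$category, "core")
  expect_equal(p168$fraction, 168 / 169)
  expect_identical(classify_prevalence(g(161), 169)$category, "soft-core")
  expect_identical(classify_prevalence(g(30), 169)$category, "accessory")
  expect_identical(classify_prevalence(g(10), 169)$category, "rare")
  # duplicate members from one genome count once
  dup <- classify_prevalence(c("g1", "g1", "g1"), 4)
  expect_identical(dup$n_genomes, 1L)
  expect_equal(dup$fraction, 0.25)
})

test_that("genera spread bins clusters and drops StORF-Only singletons", {
  clusters <- data.frame(
    cluster_id = 0:3,
    cluster_type = c("Ensembl-Only", "Ensembl-StORF", "StORF-Only",
                     "StORF-Only"),
    n_genera = c(1L, 2L, 7L, 1L),
    n_genera_storf = c(NA, 2L, NA, NA),
    n_members = c(5L, 6L, 9L, 1L),
    stringsAsFactors = FALSE)
  tab <- genera_spread(clusters)
  expect_identical(tab[tab$cluster_type == "Ensembl-Only", "1"], 1L)
  expect_identical(tab[tab$cluster_type == "Ensembl-StORF", "2"], 1L)
  expect_identical(tab[tab$cluster_type == "StORF-Only", ">6"], 1L)
  # the singleton StORF-Only cluster is excluded everywhere
  expect_identical(sum(unlist(tab[tab$cluster_type == "StORF-Only", -1])), 1L)
  # mixed clusters re-counted in the StORF row by their StORF members
  expect_identical(tab[tab$cluster_type == "StORF", "2"], 1L)
})

test_that("two-round expansion reconstructs family membership", {
  # round 1: family A spans genomes 1-3, family B genomes 4-5;
  # round 2 merges both reps with a StORF from genome 6.
  fams <- list(list(ens = list(1:3, 4:5), storf = 6L))
  fx <- generate_clstr_fixture(6, 3, fams, seed = 2)
  pg <- build_pangenome(fx$round1, fx$round2, 6)
  expect_identical(pg$clusters$cluster_type, "StORF-Combined-Ensembl")
  expect_identical(pg$clusters$n_genomes, 6L)
  expect_identical(pg$clusters$n_members, 6L)
  expect_identical(pg$clusters$prevalence_all, "core")
  # round 2 without any StORFs leaves families annotated-only, unchanged
  fams2 <- list(list(ens = list(1:3), storf = integer(0)),
                list(ens = list(4:5), storf = integer(0)))
  fx2 <- generate_clstr_fixture(6, 3, fams2, seed = 3)
  pg2 <- build_pangenome(fx2$round1, fx2$round2, 6)
  expect_identical(pg2$clusters$cluster_type,
                   rep("Ensembl-Only", 2))
  expect_identical(pg2$clusters$n_genomes, c(3L, 2L))
  # a StORF-Only cluster across 3 of 4 genomes sits at accessory 0.75
  fx3 <- generate_clstr_fixture(4, 2,
                                list(list(ens = list(), storf = 1:3)),
                                seed = 4)
  pg3 <- build_pangenome(fx3$round1, fx3$round2, 4)
  expect_identical(pg3$clusters$cluster_type, "StORF-Only")
  expect_equal(pg3$clusters$fraction, 0.75)
  expect_identical(pg3$clusters$prevalence_all, "accessory")
})

test_that("a stray round-2 member is an error", {
  fams <- list(list(ens = list(1:2), storf = integer(0)))
  fx <- generate_clstr_fixture(3, 1, fams, seed = 5)
  bad <- sub("ENSP00001", "ENSPXXXXX", fx$round2)  # no longer a round-1 rep
  expect_error(build_pangenome(fx$round1, bad, 3),
               "neither a StORF nor a round-1")
})

test_that("random fixtures classify exactly as constructed", {
  set.seed(99)
  n_genomes <- 60
  n_genera <- 6
  fams <- lapply(1:200, function(i) {
    n_sub <- sample(0:3, 1, prob = c(0.25, 0.45, 0.2, 0.1))
    ens <- if (n_sub > 0) {
      lapply(seq_len(n_sub), function(j) {
        sample(n_genomes, sample(1:20, 1))
      })
    } else list()
    n_storf <- if (n_sub >= 2) sample(1:10, 1) else sample(0:10, 1)
    storf <- if (n_storf > 0) sample(n_genomes, n_storf) else integer(0)
    if (n_sub == 0 && n_storf == 0) storf <- sample(n_genomes, 1)
    list(ens = ens, storf = storf)
  })
  fx <- generate_clstr_fixture(n_genomes, n_genera, fams, seed = 100)
  pg <- build_pangenome(fx$round1, fx$round2, n_genomes)
  cl <- pg$clusters[order(pg$clusters$cluster_id), ]
  tr <- fx$truth[order(fx$truth$cluster_id), ]
  expect_identical(cl$cluster_type, tr$cluster_type)
  expect_identical(cl$prevalence_all, tr$prevalence_all)
  expect_equal(cl$fraction, tr$fraction)
  expect_identical(cl$n_genomes, tr$n_genomes)
  expect_identical(cl$n_genera, tr$n_genera)
  expect_identical(cl$n_members, tr$n_members)
  expect_identical(cl$prevalence_storf_only, tr$prevalence_storf_only)
  # conservation: expansion loses no sequence
  r1 <- parse_cdhit_clstr(fx$round1)
  r2 <- parse_cdhit_clstr(fx$round2)
  n_storf_seqs <- sum(grepl("StORF", r2$seq_id, fixed = TRUE))
  expect_identical(sum(cl$n_members), nrow(r1) + n_storf_seqs)
  # partition: exactly one type and one band per family
  expect_true(all(cl$cluster_type %in%
                    c("Ensembl-Only", "Ensembl-StORF",
                      "StORF-Combined-Ensembl", "StORF-Only")))
  expect_true(all(cl$prevalence_all %in%
                    c("core", "soft-core", "accessory", "rare")))
  # summary recount equals a brute tally
  for (ty in unique(cl$cluster_type)) {
    for (band in c("core", "soft-core", "accessory", "rare")) {
      expect_identical(
        pg$summary[pg$summary$cluster_type == ty, band],
        sum(cl$cluster_type == ty & cl$prevalence_all == band),
        label = paste(ty, band))
    }
  }
  # genera table recount
  brute <- genera_spread(cl)
  expect_identical(pg$genera, brute)
})

test_that("raising the core threshold never increases the core count", {
  set.seed(7)
  fams <- lapply(1:40, function(i) {
    list(ens = list(sample(50, sample(1:50, 1))), storf = integer(0))
  })
  fx <- generate_clstr_fixture(50, 5, fams, seed = 7)
  cores <- vapply(c(0.90, 0.95, 0.99, 1.0), function(thr) {
    pg <- build_pangenome(fx$round1, fx$round2, 50,
                          thresholds = c(core = thr, soft_core = 0.85,
                                         accessory = 0.15))
    sum(pg$summary$core)
  }, integer(1))
  expect_true(all(diff(cores) <= 0))
})
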