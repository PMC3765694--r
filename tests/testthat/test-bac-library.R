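# HindIII digestion, clone sampling and the probe screen.

test_that("HindIII digestion cuts at A^AGCTT and conserves length", {
  expect_equal(digest_hindiii("TTTAAGCTTGGG"), c(4L, 8L))
  expect_equal(digest_hindiii("GGGGGGG"), 7L)
  two <- digest_hindiii(paste0("CC", "AAGCTT", "TTTT", "AAGCTT", "GGG"))
  expect_equal(length(two), 3L)
  expect_equal(sum(two), 2 + 6 + 4 + 6 + 3)
  expect_error(digest_hindiii("ACGTN"), "non-ACGT")
  set.seed(3)
  for (rep in 1:20) {
    s <- random_dna_str(sample(50:3000, 1))
    expect_equal(sum(digest_hindiii(s)), nchar(s))
  }
})

test_that("clone sampling respects the empty rate, coverage and seed", {
  set.seed(5)
  g <- random_dna_str(300000)
  all_empty <- simulate_bac_library(g, bac_library_params(
    n_clones = 20, insert_mean_bp = 30000, insert_sd_bp = 2000,
    empty_clone_prob = 1, seed = 6))
  expect_true(all(all_empty$clones$empty))
  expect_true(all(lengths(all_empty$fingerprints) == 0))
  # n x insert = 10 x genome length -> coverage 10.0 by definition
  expect_equal(library_coverage(100, 30000, 300000), 10)
  lib1 <- simulate_bac_library(g, bac_library_params(
    n_clones = 25, insert_mean_bp = 30000, empty_clone_prob = 0, seed = 9))
  lib2 <- simulate_bac_library(g, bac_library_params(
    n_clones = 25, insert_mean_bp = 30000, empty_clone_prob = 0, seed = 9))
  expect_identical(lib1$clones, lib2$clones)
  expect_identical(lib1$fingerprints, lib2$fingerprints)
  expect_true(all(lib1$clones$start >= 1 & lib1$clones$end <= 300000))
  expect_error(simulate_bac_library(random_dna_str(1000), bac_library_params(
    n_clones = 5, insert_mean_bp = 30000)), "longer than")
})

test_that("probe screen counts overlaps, loci and redundancy", {
  clones <- data.frame(id = c("c1", "c2", "c3"),
                       start = c(1, 5000, 20000), end = c(6000, 11000, 26000),
                       empty = c(FALSE, FALSE, FALSE))
  loci <- data.frame(probe = c("p1", "p1", "p2"),
                     start = c(5500, 24000, 40000), end = c(5900, 25500, 41000))
  sc <- simulate_probe_screen(clones, loci, min_overlap_bp = 300)
  tab <- sc$table
  expect_equal(tab$n_positive[tab$probe == "p1"], 3L)
  expect_equal(tab$n_loci[tab$probe == "p1"], 2L)
  expect_equal(tab$mean_redundancy[tab$probe == "p1"], 1.5)
  expect_equal(tab$n_positive[tab$probe == "p2"], 0L)
  # probe with no retained locus: zero positives, zero loci, no error
  sc2 <- simulate_probe_screen(clones, loci, min_overlap_bp = 300,
                               probes = c("p1", "p2", "gone"))
  expect_equal(sc2$table$n_loci[sc2$table$probe == "gone"], 0L)
  expect_equal(sc2$table$n_positive[sc2$table$probe == "gone"], 0L)
  # abutting below the overlap threshold is negative
  edge <- data.frame(id = "e1", start = 1, end = 1000, empty = FALSE)
  locus <- data.frame(probe = "p", start = 950, end = 2000)
  expect_equal(simulate_probe_screen(edge, locus,
                                     min_overlap_bp = 100)$table$n_positive, 0L)
  expect_equal(simulate_probe_screen(edge, locus,
                                     min_overlap_bp = 51)$table$n_positive, 1L)
  # empty clones never hybridise
  clones$empty[1] <- TRUE
  expect_equal(simulate_probe_screen(clones, loci,
                                     min_overlap_bp = 300)$table$n_positive[1], 2L)
})

test_that("single-copy probe positives average to the library coverage", {
  # closed-form check: clone starts are uniform, so the expected number of
  # positives for one locus is n * (insert + locus - 2 overlap + 1) / (L - insert + 1),
  # which approaches the fold coverage for a point locus
  set.seed(17)
  L <- 1e6; insert <- 50000; n <- 60  # 3x coverage
  locus <- data.frame(probe = "p", start = 500000, end = 502000)
  min_ov <- 1000
  hits <- vapply(1:200, function(r) {
    start <- sample.int(L - insert + 1L, n, replace = TRUE)
    clones <- data.frame(id = paste0("c", 1:n), start = start,
                         end = start + insert - 1L)
    simulate_probe_screen(clones, locus, min_overlap_bp = min_ov)$table$n_positive
  }, 0L)
  width <- (locus$end - min_ov + 1) - (locus$start - insert + min_ov) + 1
  expected <- n * width / (L - insert + 1L)
  # Monte-Carlo standard error over 200 replicates is ~4% of the mean
  expect_lt(abs(mean(hits) - expected) / expected, 0.12)
  expect_lt(abs(mean(hits) - library_coverage(n, insert, L)) / expected, 0.2)
})

test_that("concatenated genomes expose per-copy gene loci at offsets", {
  sim <- simulate_ancestral_region(4, seed = 2)
  ev <- evolve_polyploid_genomes(sim, evolution_params(
    t_wgt_mya = 1, t_b_split_mya = 0.5, t_ac_split_mya = 0.2,
    exon_del_prob_per_branch = 0, n_inversions = 0, n_tandem_dups = 0,
    n_foreign_insertions = 0, n_te_insertions = 0, seed = 3))
  bc <- ev$copies[grep("^B_", names(ev$copies))]
  cg <- concat_genome(bc, spacer_bp = 5000, seed = 4)
  expect_equal(length(cg$offsets), 3L)
  expect_equal(nrow(cg$loci), 12L)  # 4 genes x 3 copies
  # locus sequence at the concatenated coordinates equals the copy's gene
  l1 <- cg$loci[cg$loci$copy == "B_MF1", ][1, ]
  g1 <- bc$B_MF1$genes[bc$B_MF1$genes$ancestral_id == l1$probe, ]
  expect_equal(substring(cg$sequence, l1$start, l1$end),
               substring(bc$B_MF1$sequence, g1$start, g1$end))
})
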