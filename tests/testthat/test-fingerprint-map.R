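# Band matching, Sulston scores and stepwise contig assembly.

test_that("band matching is greedy one-to-one in ascending order", {
  expect_equal(match_bands(1:30 * 40, 1:30 * 40, 3), 30L)
  expect_equal(match_bands(c(10, 20, 30), c(100, 200), 3), 0L)
  expect_equal(match_bands(c(100, 104), c(102), 3), 1L)
  expect_equal(match_bands(c(100, 104), c(102, 104.5), 3), 2L)
  expect_equal(match_bands(numeric(0), c(1, 2), 3), 0L)
})

test_that("Sulston scores match a direct binomial evaluation and its properties", {
  set.seed(5)
  fp1 <- sort(runif(30, 20, 1200))
  fp2 <- sort(runif(25, 20, 1200))
  p <- function(nH) 1 - (1 - 2 * 3 / 1180)^nH
  m <- match_bands(fp1, fp2, 3)
  expect_equal(sulston_score(fp1, fp2), oracle_sulston_tail(m, 25, p(30)))
  # identical fingerprints: full-match tail term
  expect_equal(sulston_score(fp1, fp1), oracle_sulston_tail(30, 30, p(30)))
  expect_lt(sulston_score(fp1, fp1), 1e-20)
  # no shared bands: normalisation to 1
  expect_equal(sulston_score(c(100), c(500)), 1)
  # symmetry
  expect_equal(sulston_score(fp1, fp2), sulston_score(fp2, fp1))
  # monotone non-increasing in m at fixed band counts
  tails <- vapply(0:25, function(m) oracle_sulston_tail(m, 25, p(30)), 0)
  expect_true(all(diff(tails) <= 0))
  expect_error(sulston_score(fp1, fp2, tolerance = 600), "tolerance")
})

test_that("disjoint fingerprints stay singletons; degenerate schedule works", {
  fps <- lapply(0:9, function(i) sort(20 + (i * 117 + c(1, 5, 9, 13) * 7) %% 1180))
  names(fps) <- paste0("c", 1:10)
  ct <- assemble_stepwise(fps, assembly_params())
  expect_equal(length(ct$contigs), 0L)
  expect_equal(sort(ct$singletons), sort(names(fps)))
  # single-pass schedule
  ct2 <- assemble_stepwise(fps, assembly_params(cutoff_start = 1e-20,
                                                cutoff_end = 1e-20))
  expect_equal(ct2$cutoffs, 1e-20)
})

test_that("agglomeration is monotone in the cutoff before DQer re-splits", {
  set.seed(8)
  genome <- random_dna_str(400000)
  lib <- simulate_bac_library(genome, bac_library_params(
    n_clones = 40, insert_mean_bp = 60000, insert_sd_bp = 5000,
    empty_clone_prob = 0, seed = 13))
  n_components <- vapply(c(1e-35, 1e-30, 1e-25, 1e-20, 1e-15), function(cut) {
    ct <- assemble_stepwise(lib$fingerprints,
                            assembly_params(cutoff_start = cut, cutoff_end = cut,
                                            dq_fraction = 0.99))
    length(ct$contigs) + length(ct$singletons)
  }, 0)
  expect_true(all(diff(n_components) <= 0))
})

test_that("clones from unlinked regions are never co-assembled", {
  set.seed(21)
  for (rep in 1:5) {
    g1 <- random_dna_str(250000)
    g2 <- random_dna_str(250000)
    lib1 <- simulate_bac_library(g1, bac_library_params(
      n_clones = 15, insert_mean_bp = 60000, insert_sd_bp = 5000,
      empty_clone_prob = 0, seed = 100 + rep))
    lib2 <- simulate_bac_library(g2, bac_library_params(
      n_clones = 15, insert_mean_bp = 60000, insert_sd_bp = 5000,
      empty_clone_prob = 0, seed = 200 + rep))
    fps <- c(lib1$fingerprints, lib2$fingerprints)
    names(fps) <- c(paste0("r1_", seq_len(15)), paste0("r2_", seq_len(15)))
    ct <- assemble_stepwise(fps, assembly_params())
    for (ctg in ct$contigs) {
      expect_true(all(startsWith(ctg, "r1_")) || all(startsWith(ctg, "r2_")))
    }
  }
})

test_that("assembly evaluation follows the stated conventions", {
  truth <- data.frame(id = c("a", "b", "c", "d"),
                      start = c(1, 20000, 500000, 520000),
                      end = c(130000, 150000, 630000, 650000))
  perfect <- structure(list(contigs = list(ctg1 = c("a", "b"),
                                           ctg2 = c("c", "d")),
                            singletons = character(0), q_clones = character(0),
                            q_fraction = c(0, 0), cutoffs = 1e-15),
                       class = "contig_set")
  ev <- evaluate_assembly(perfect, truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  all_single <- structure(list(contigs = list(),
                               singletons = truth$id, q_clones = character(0),
                               q_fraction = numeric(0), cutoffs = 1e-15),
                          class = "contig_set")
  ev0 <- evaluate_assembly(all_single, truth)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$precision, 1)
  expect_false(ev0$precision_defined)
  wrong <- structure(list(contigs = list(ctg1 = c("a", "c")),
                          singletons = c("b", "d"), q_clones = character(0),
                          q_fraction = 0, cutoffs = 1e-15),
                     class = "contig_set")
  expect_equal(evaluate_assembly(wrong, truth)$precision, 0)
})
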