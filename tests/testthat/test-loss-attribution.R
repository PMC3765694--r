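# Dollo-parsimony loss placement and the branch-partitioned
# fractionation report.

test_that("Dollo assignment equals the 2^5 placement enumeration for all patterns", {
  pats <- expand.grid(A = c(TRUE, FALSE), B = c(TRUE, FALSE),
                      C = c(TRUE, FALSE))
  for (r in seq_len(nrow(pats))) {
    pat <- c(A = pats$A[r], B = pats$B[r], C = pats$C[r])
    got <- dollo_assign(pat)
    minima <- oracle_dollo(pat)
    expect_equal(length(minima), 1L, info = paste(pat, collapse = ","))
    expect_setequal(got, minima[[1L]])
  }
  # the worked placements
  expect_equal(dollo_assign(c(A = TRUE, B = TRUE, C = TRUE)), character(0))
  expect_equal(dollo_assign(c(A = FALSE, B = FALSE, C = FALSE)), "stem_ABC")
  expect_equal(dollo_assign(c(A = FALSE, B = TRUE, C = FALSE)), "stem_AC")
  expect_setequal(dollo_assign(c(A = FALSE, B = FALSE, C = TRUE)),
                  c("term_A", "term_B"))
})

# small handmade presence matrix helper
toy_matrix <- function(retained, genes, exons) {
  structure(list(
    rows = data.frame(gene = genes, exon = exons, stringsAsFactors = FALSE),
    retained = retained,
    identity = ifelse(retained, 100, NA_real_),
    coverage = ifelse(retained, 1, NA_real_),
    hits = NULL, min_id = 70, min_cov = 0.5), class = "presence_matrix")
}

test_that("branch report tallies Dollo losses with additive counts", {
  copies <- as.vector(outer(c("A", "B", "C"), c("LF", "MF1", "MF2"),
                            paste, sep = "_"))
  genes <- paste0("g", 1:4)
  ret <- matrix(TRUE, 4, 9, dimnames = list(NULL, copies))
  # g1 lost everywhere in MF2 -> stem_ABC; g2 lost in A,C of LF -> stem_AC;
  # g3 lost in B of MF1 -> term_B; g4 intact
  ret[1, c("A_MF2", "B_MF2", "C_MF2")] <- FALSE
  ret[2, c("A_LF", "C_LF")] <- FALSE
  ret[3, "B_MF1"] <- FALSE
  m <- toy_matrix(ret, genes, rep(1L, 4))
  rep_ <- branch_fractionation(m)
  expect_equal(rep_$counts["stem_ABC", "MF2"], 1L)
  expect_equal(rep_$counts["stem_AC", "LF"], 1L)
  expect_equal(rep_$counts["term_B", "MF1"], 1L)
  expect_equal(sum(rep_$counts), 3L)
  expect_equal(rep_$pct["stem_ABC", "MF2"], 25)
  # additivity: total branch losses = total per-pattern Dollo costs
  costs <- 0L
  for (cp in c("LF", "MF1", "MF2")) {
    for (g in seq_along(genes)) {
      pat <- c(A = unname(ret[g, paste0("A_", cp)]),
               B = unname(ret[g, paste0("B_", cp)]),
               C = unname(ret[g, paste0("C_", cp)]))
      costs <- costs + length(dollo_assign(pat))
    }
  }
  expect_equal(sum(rep_$counts), costs)
  # row-order invariance
  ord <- c(3, 1, 4, 2)
  m2 <- toy_matrix(ret[ord, ], genes[ord], rep(1L, 4))
  expect_equal(branch_fractionation(m2)$counts, rep_$counts)
  # zero-loss matrix
  m0 <- toy_matrix(matrix(TRUE, 4, 9, dimnames = list(NULL, copies)),
                   genes, rep(1L, 4))
  expect_true(all(branch_fractionation(m0)$counts == 0L))
})

test_that("forced stem losses land entirely on the forced branch", {
  sim <- simulate_ancestral_region(10, seed = 3)
  # deletions only on stem_ABC: terminal branches have zero length relative
  # to the stem, so every loss is shared by all three genomes
  ev <- evolve_polyploid_genomes(sim, evolution_params(
    t_wgt_mya = 8, t_b_split_mya = 0, t_ac_split_mya = 0,
    exon_del_prob_per_branch = 0.2,
    n_inversions = 0, n_tandem_dups = 0, n_foreign_insertions = 0,
    n_te_insertions = 0, mu = 0, seed = 4))
  expect_true(nrow(ev$truth$loss_events) > 0)
  expect_true(all(ev$truth$loss_events$branch == "stem_ABC"))
  pm <- presence_from_annotation(sim, ev$copies)
  rep_ <- branch_fractionation(pm)
  expect_true(all(rep_$counts[c("stem_AC", "term_A", "term_B", "term_C"), ] == 0L))
  # gene-level losses equal genes whose exons were all deleted on the stem
  expect_equal(sum(rep_$counts["stem_ABC", ]),
               sum(!tapply(pm$retained[, "A_LF"], pm$rows$gene, any)) +
                 sum(!tapply(pm$retained[, "A_MF1"], pm$rows$gene, any)) +
                 sum(!tapply(pm$retained[, "A_MF2"], pm$rows$gene, any)))
})

test_that("sub-genome ranking orders by retention with deterministic ties", {
  mk <- function(copy, exon_pct, genic_pct) {
    structure(list(copy = copy, retained_exons_pct = exon_pct,
                   retained_genic_pct = genic_pct), class = "region_stats")
  }
  r <- rank_subgenomes(list(mk("c1", 74, 90), mk("c2", 53, 70), mk("c3", 38, 50)))
  expect_equal(unname(r), c("LF", "MF1", "MF2"))
  expect_equal(names(r), c("c1", "c2", "c3"))
  # all equal: lexicographic copy id breaks the tie
  r2 <- rank_subgenomes(list(mk("z", 50, 50), mk("a", 50, 50), mk("m", 50, 50)))
  expect_equal(names(r2), c("a", "m", "z"))
  # genic percentage breaks an exon-percentage tie
  r3 <- rank_subgenomes(list(mk("x", 50, 40), mk("y", 50, 60), mk("w", 20, 20)))
  expect_equal(names(r3), c("y", "x", "w"))
  expect_error(rank_subgenomes(list(mk("a", 1, 1))), "3 copies")
})
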