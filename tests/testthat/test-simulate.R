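# The ancestral-region generator and the polyploid evolution engine.

test_that("ancestral regions satisfy the coding-gene construction invariants", {
  sim <- simulate_ancestral_region(17, seed = 1)
  expect_s3_class(sim, "genome_copy")
  expect_equal(nrow(sim$genes), 17L)
  expect_equal(sim$genes$id, paste0("g", 1:17))
  expect_true(all(diff(sim$genes$start) > 0))  # ids in coordinate order
  code <- Biostrings::GENETIC_CODE
  for (g in sim$genes$id) {
    cds <- gene_cds(sim, g)
    expect_equal(nchar(cds) %% 3, 0)
    aa <- code[substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))]
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_equal(unname(aa[length(aa)]), "*")
    expect_false(any(aa[-length(aa)] == "*"))
  }
  # exon intervals: sorted, non-overlapping, within bounds
  for (g in sim$genes$id) {
    ex <- sim$exons[sim$exons$gene_id == g, ]
    ex <- ex[order(ex$start), ]
    expect_true(all(ex$start <= ex$end))
    if (nrow(ex) > 1) expect_true(all(ex$start[-1] > ex$end[-nrow(ex)]))
    expect_true(all(ex$end <= nchar(sim$sequence)))
  }
  # single 300-bp exon case
  one <- simulate_ancestral_region(1, mean_exons_per_gene = 1,
                                   mean_exon_len = 300, seed = 2)
  expect_equal(nrow(one$genes), 1L)
  expect_error(simulate_ancestral_region(0), "n_genes")
  expect_error(simulate_ancestral_region(3, mean_exon_len = -1), "positive")
})

test_that("a fixed seed reproduces the region byte for byte", {
  a <- simulate_ancestral_region(8, seed = 77)
  b <- simulate_ancestral_region(8, seed = 77)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$genes, b$genes)
  expect_identical(a$exons, b$exons)
  c2 <- simulate_ancestral_region(8, seed = 78)
  expect_false(identical(a$sequence, c2$sequence))
})

test_that("zero ages and zero event counts give nine identical copies", {
  sim <- simulate_ancestral_region(6, seed = 10)
  ev <- evolve_polyploid_genomes(sim, evolution_params(
    t_wgt_mya = 0, t_b_split_mya = 0, t_ac_split_mya = 0,
    n_inversions = 0, n_tandem_dups = 0, n_foreign_insertions = 0,
    n_te_insertions = 0, seed = 3))
  expect_equal(length(ev$copies), 9L)
  for (cp in ev$copies) {
    expect_identical(cp$sequence, sim$sequence)
    expect_equal(cp$exons, sim$exons)
  }
  expect_equal(nrow(ev$truth$loss_events), 0L)
  expect_equal(nrow(ev$truth$rearrangements), 0L)
  expect_identical(ev$ref$sequence, sim$sequence)
})

test_that("evolution is deterministic under a fixed seed", {
  sim <- simulate_ancestral_region(6, seed = 11)
  p <- evolution_params(seed = 123)
  e1 <- evolve_polyploid_genomes(sim, p)
  e2 <- evolve_polyploid_genomes(sim, p)
  expect_identical(lapply(e1$copies, `[[`, "sequence"),
                   lapply(e2$copies, `[[`, "sequence"))
  expect_identical(e1$truth$loss_events, e2$truth$loss_events)
  expect_identical(e1$truth$rearrangements, e2$truth$rearrangements)
})

test_that("loss bookkeeping: surviving + deleted exons equal the ancestral count", {
  sim <- simulate_ancestral_region(12, seed = 6)
  ev <- evolve_polyploid_genomes(sim, evolution_params(
    exon_del_prob_per_branch = 0.08, mu = 0,
    n_inversions = 0, n_tandem_dups = 0, n_foreign_insertions = 0,
    n_te_insertions = 0, seed = 8))
  losses <- ev$truth$loss_events
  tip_paths <- list(A = c("stem_ABC", "stem_AC", "term_A"),
                    B = c("stem_ABC", "term_B"),
                    C = c("stem_ABC", "stem_AC", "term_C"))
  for (genome in c("A", "B", "C")) {
    for (cp in c("LF", "MF1", "MF2")) {
      tip <- ev$copies[[paste(genome, cp, sep = "_")]]
      for (g in sim$genes$id) {
        anc_n <- sum(sim$exons$gene_id == g)
        kept <- sum(tip$exons$gene_id == g)
        del <- sum(losses$gene == g & losses$copy == cp &
                     losses$branch %in% tip_paths[[genome]])
        expect_equal(kept + del, anc_n,
                     info = paste(genome, cp, g))
      }
    }
  }
  # no deletion is logged twice
  expect_false(any(duplicated(losses)))
})

test_that("expected pairwise Ks entries follow the clock exactly", {
  sim <- simulate_ancestral_region(3, seed = 20)
  p <- evolution_params(seed = 1)
  ev <- evolve_polyploid_genomes(sim, p)
  ks <- ev$truth$expected_ks
  expect_equal(ks$expected_ks, 2 * p$mu * 1e6 * ks$t_mya)
  expect_equal(ks$expected_ks[ks$split == "ac_split"], 0.096)
  expect_equal(ks$expected_ks[ks$split == "wgt"], 0.348)
  expect_false(ev$truth$saturation_warning)
  # deep ages beyond Ks 1 raise the saturation warning
  deep <- evolve_polyploid_genomes(sim, evolution_params(
    t_wgt_mya = 40, t_b_split_mya = 6.2, t_ac_split_mya = 3.2, seed = 1))
  expect_true(deep$truth$saturation_warning)
})

test_that("realised synonymous divergence tracks the clock", {
  # moderately sized simulation; each pair's Ks should sit near 2 mu T
  sim <- simulate_ancestral_region(40, mean_exons_per_gene = 2,
                                   mean_exon_len = 210, seed = 31)
  ev <- evolve_polyploid_genomes(sim, evolution_params(
    exon_del_prob_per_branch = 0, n_inversions = 0, n_tandem_dups = 0,
    n_foreign_insertions = 0, n_te_insertions = 0, seed = 32))
  ks_between <- function(x, y) {
    vals <- vapply(sim$genes$id, function(g) {
      estimate_ks_ka(codon_align(gene_cds(x, g), gene_cds(y, g)))$ks
    }, 0)
    mean(vals, na.rm = TRUE)
  }
  k_ac <- ks_between(ev$copies$A_LF, ev$copies$C_LF)
  expect_lt(abs(k_ac - 0.096), 0.15 * 0.096 + 0.01)
  k_ab <- ks_between(ev$copies$A_MF1, ev$copies$B_MF1)
  expect_lt(abs(k_ab - 0.186), 0.15 * 0.186)
  k_wgt <- ks_between(ev$copies$B_LF, ev$copies$B_MF2)
  expect_lt(abs(k_wgt - 0.348), 0.15 * 0.348)
})

test_that("structural events are applied and logged once each", {
  sim <- simulate_ancestral_region(14, seed = 41)
  ev <- evolve_polyploid_genomes(sim, evolution_params(
    n_inversions = c(stem_AC = 1), n_tandem_dups = c(term_B = 1),
    n_foreign_insertions = c(term_C = 2), n_te_insertions = c(term_A = 1),
    exon_del_prob_per_branch = 0, seed = 42))
  re <- ev$truth$rearrangements
  expect_equal(sum(re$type == "inversion"), 1L)
  expect_equal(sum(re$type == "tandem_dup"), 1L)
  expect_equal(sum(re$type == "foreign_insertion"), 2L)
  expect_equal(sum(re$type == "te_insertion"), 1L)
  # the tandem duplication doubles that gene's loci in the B tip
  dup_gene <- re$detail[re$type == "tandem_dup"]
  dup_copy <- re$copy[re$type == "tandem_dup"]
  tip <- ev$copies[[paste0("B_", dup_copy)]]
  expect_equal(sum(tip$genes$ancestral_id %in% dup_gene), 2L)
  # the inversion is shared by A and C (stem_AC) but absent from B
  inv_copy <- re$copy[re$type == "inversion"]
  om <- ev$truth$ortholog_map
  expect_true(all(c("A", "B", "C") %in% om$genome))
  # TE insertions appear as TE intervals in the A tip annotation
  te_copy <- re$copy[re$type == "te_insertion"]
  expect_equal(nrow(ev$copies[[paste0("A_", te_copy)]]$tes), 1L)
})
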