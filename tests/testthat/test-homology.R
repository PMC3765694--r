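# Local alignment (exact and seeded) and ortholog/locus detection.

test_that("self and reverse-complement alignments are perfect hits", {
  set.seed(2)
  q <- random_dna_str(50)
  h <- align_local(q, q)
  expect_equal(h$score, 50)
  expect_equal(h$identity, 100)
  expect_equal(h$strand, "+")
  expect_equal(h$coverage, 1)
  h2 <- align_local(q, revcomp(q))
  expect_equal(h2$identity, 100)
  expect_equal(h2$strand, "-")
  expect_error(align_local("ACGT", "ACNGT"), "non-ACGT")
})

test_that("exact mode matches the Smith-Waterman oracle; seeded is bounded by it", {
  set.seed(33)
  for (rep in 1:25) {
    q <- random_dna_str(30)
    t <- random_dna_str(30)
    h <- align_local(q, t, mode = "exact_sw")
    oracle <- oracle_sw_score_2str(q, t)
    expect_equal(h$score, oracle)
    hs <- align_local(q, t, mode = "seeded")
    if (!is.null(hs)) expect_lte(hs$score, oracle)
  }
  # a planted exact region guarantees a seed, hence seeded equality
  for (rep in 1:5) {
    core <- random_dna_str(25)
    q <- paste0(random_dna_str(5), core, random_dna_str(5))
    t <- paste0(random_dna_str(200), core, random_dna_str(200))
    e <- align_local(q, t, mode = "exact_sw")
    s <- align_local(q, t, mode = "seeded")
    expect_equal(s$score, e$score)
  }
})

# shared fixture: a moderately diverged triplicated set with no losses
fixture_clean <- local({
  sim <- simulate_ancestral_region(6, seed = 55)
  ev <- evolve_polyploid_genomes(sim, evolution_params(
    exon_del_prob_per_branch = 0, n_inversions = 0, n_tandem_dups = 0,
    n_foreign_insertions = 0, n_te_insertions = 0, seed = 56))
  list(sim = sim, ev = ev)
})

test_that("with no losses every exon is found at exactly one locus per copy", {
  sim <- fixture_clean$sim
  for (nm in c("A_LF", "B_MF1", "C_MF2")) {
    hits <- find_orthologs(sim, fixture_clean$ev$copies[[nm]])
    key <- paste(hits$gene, hits$exon)
    expect_setequal(key, paste(sim$exons$gene_id, sim$exons$anc_index))
    expect_false(any(duplicated(key)))
    expect_true(all(hits$locus == 1L))
    expect_true(all(hits$identity >= 70))
  }
})

test_that("deleted exons yield no hits; tandem duplications yield two loci", {
  sim <- simulate_ancestral_region(8, seed = 61)
  ev <- evolve_polyploid_genomes(sim, evolution_params(
    t_wgt_mya = 2, t_b_split_mya = 1, t_ac_split_mya = 0.5,
    exon_del_prob_per_branch = 0.12,
    n_inversions = 0, n_tandem_dups = c(term_B = 1),
    n_foreign_insertions = 0, n_te_insertions = 0, seed = 62))
  tr <- ev$truth
  dup_gene <- tr$rearrangements$detail[tr$rearrangements$type == "tandem_dup"]
  dup_copy <- tr$rearrangements$copy[tr$rearrangements$type == "tandem_dup"]
  tip <- ev$copies[[paste0("B_", dup_copy)]]
  hits <- find_orthologs(sim, tip)
  # truth absences have no hit rows
  lost <- tr$loss_events[tr$loss_events$copy == dup_copy &
                           tr$loss_events$branch %in% c("stem_ABC", "term_B"), ]
  dup_rows <- hits[hits$gene == dup_gene, ]
  if (nrow(dup_rows)) {
    expect_equal(max(dup_rows$locus), 2L)
  }
  for (r in seq_len(nrow(lost))) {
    expect_false(any(hits$gene == lost$gene[r] & hits$exon == lost$exon[r] &
                       hits$gene != dup_gene))
  }
})

test_that("presence matrix equals truth deletions and is threshold-monotone", {
  sim <- simulate_ancestral_region(8, seed = 71)
  ev <- evolve_polyploid_genomes(sim, evolution_params(
    t_wgt_mya = 2, t_b_split_mya = 1, t_ac_split_mya = 0.5,
    exon_del_prob_per_branch = 0.12,
    n_inversions = 0, n_tandem_dups = 0, n_foreign_insertions = 0,
    n_te_insertions = 0, seed = 72))
  pm <- build_presence_matrix(sim, ev$copies)
  truth_pm <- presence_from_annotation(sim, ev$copies)
  expect_identical(pm$retained, truth_pm$retained)
  # monotone: raising thresholds never adds a retained cell
  for (pars in list(c(80, 0.6), c(90, 0.8), c(99, 0.95))) {
    stricter <- rethreshold_presence(pm, pars[1], pars[2])
    expect_true(all(pm$retained | !stricter$retained))
  }
  # impossible identity threshold empties the matrix
  none <- rethreshold_presence(pm, 101, 0.5)
  expect_false(any(none$retained))
})
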