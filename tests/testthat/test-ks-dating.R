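# NG86 site counting, pathway-averaged differences, Jukes-Cantor
# correction and clock dating.

test_that("synonymous site fractions match exhaustive mutation enumeration", {
  expect_equal(sum(count_sites_ng86("TTT")), 1 / 3)
  expect_equal(sum(count_sites_ng86("ATG")), 0)
  expect_equal(sum(count_sites_ng86("GGG")), 1)
  code <- Biostrings::GENETIC_CODE
  for (codon in names(code)[code != "*"]) {
    expect_equal(sum(count_sites_ng86(codon)), oracle_syn_sites(codon),
                 info = codon)
  }
  expect_error(count_sites_ng86("TAA"), "stop")
})

test_that("codon alignment drops gap columns and rejects internal stops", {
  set.seed(1)
  a <- random_cds(100)
  al <- codon_align(a, a)
  expect_equal(al$n_codons, 99)  # terminal stop trimmed
  expect_identical(al$codons_a, al$codons_b)
  # delete one codon from b: one gap column dropped
  b <- paste0(substr(a, 1, 30), substr(a, 34, nchar(a)))
  al2 <- codon_align(a, b)
  expect_equal(al2$n_codons, 98)
  bad <- paste0("ATGTAAGGG", "TAA")
  expect_error(codon_align(a, bad), "internal stop")
})

test_that("protein alignment scoring agrees with a full DP oracle", {
  set.seed(42)
  for (rep in 1:8) {
    a <- random_cds(sample(10:30, 1))
    b <- random_cds(sample(10:30, 1))
    al <- codon_align(a, b)
    pa <- paste(Biostrings::GENETIC_CODE[substring(
      a, seq(1, nchar(a) - 3, 3), seq(3, nchar(a) - 1, 3))], collapse = "")
    pb <- paste(Biostrings::GENETIC_CODE[substring(
      b, seq(1, nchar(b) - 3, 3), seq(3, nchar(b) - 1, 3))], collapse = "")
    expect_equal(al$score, oracle_nw_protein_score(pa, pb))
  }
})

test_that("Ks/Ka estimates match the pathway-enumeration oracle", {
  set.seed(7)
  # identical sequences
  a <- random_cds(50)
  e0 <- estimate_ks_ka(codon_align(a, a))
  expect_equal(e0$ks, 0)
  expect_equal(e0$ka, 0)
  expect_equal(e0$S + e0$N, 3 * e0$n_codons)
  # a single synonymous difference in a 10-codon alignment
  a1 <- "ATGGCTAAAGGTTGGCCTACTGATCATTAA"   # 10 codons incl stop
  b1 <- sub("GCT", "GCC", a1)              # Ala GCT->GCC, synonymous
  al <- codon_align(a1, b1)
  e1 <- estimate_ks_ka(al)
  expect_equal(e1$Sd, 1)
  expect_equal(e1$Nd, 0)
  S <- (sum(vapply(substring(a1, seq(1, 27, 3), seq(3, 29, 3)),
                   function(cd) sum(count_sites_ng86(cd)), 0)) +
        sum(vapply(substring(b1, seq(1, 27, 3), seq(3, 29, 3)),
                   function(cd) sum(count_sites_ng86(cd)), 0))) / 2
  expect_equal(e1$ks, -0.75 * log(1 - 4 / 3 * (1 / S)))
  # two-difference codon TTT <-> CTC: average over both orderings
  pd <- oracle_ng86_pair("TTT", "CTC")
  a2 <- paste0("ATG", "TTT", "TAA")
  b2 <- paste0("ATG", "CTC", "TAA")
  e2 <- estimate_ks_ka(codon_align(a2, b2))
  expect_equal(e2$Sd, unname(pd["sd"]))
  expect_equal(e2$Nd, unname(pd["nd"]))
})

test_that("estimates are symmetric and saturation is flagged, not thrown", {
  set.seed(11)
  for (rep in 1:5) {
    a <- random_cds(40)
    b <- random_cds(40)
    ea <- estimate_ks_ka(codon_align(a, b))
    eb <- estimate_ks_ka(codon_align(b, a))
    expect_equal(ea$Sd, eb$Sd)
    expect_equal(ea$Nd, eb$Nd)
    expect_equal(ea$ks, eb$ks)
    expect_equal(ea$S + ea$N, 3 * ea$n_codons)
  }
  # random CDS pairs are far beyond saturation
  a <- random_cds(60); b <- random_cds(60)
  es <- estimate_ks_ka(codon_align(a, b))
  if (es$pN >= 0.75 || es$pS >= 0.75) {
    expect_true(es$saturated)
    expect_true(is.na(es$ka) || is.na(es$ks) ||
                  (es$pS < 0.75 && es$pN < 0.75))
  }
})

test_that("Jukes-Cantor correction is monotone on [0, 3/4)", {
  p <- seq(0, 0.74, by = 0.02)
  d <- -0.75 * log(1 - 4 * p / 3)
  expect_true(all(diff(d) > 0))
  expect_true(all(d[-1] > p[-1]))  # correction always inflates
})

test_that("clock dating is the exact closed form", {
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(0.30), 10)
  expect_equal(divergence_time(0.096), 3.2)
  expect_error(divergence_time(-0.1), "non-negative")
})

test_that("pairwise summaries average per-gene times, not the mean Ks", {
  s1 <- summarize_pairwise(0.18)
  expect_equal(s1$mean_mya, 6)
  expect_equal(s1$sd_mya, 0)
  s2 <- summarize_pairwise(c(0.15, 0.21))
  expect_equal(s2$mean_ks, 0.18)
  expect_equal(s2$mean_mya, 6)
  expect_equal(s2$sd_mya, 1)  # population sd of (5, 7)
  expect_error(summarize_pairwise(c(NA_real_, NA_real_)), "no unsaturated")
})
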