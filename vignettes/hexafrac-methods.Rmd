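---
title: "Models and methods behind hexafrac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hexafrac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexafrac)
```

hexafrac studies what happens to a genomic region after a whole-genome
triplication (WGT) of the kind shared by the Brassiceae: three homologous
copies of each ancestral region (sub-genomes) persist in every descendant
genome and are progressively *fractionated* — duplicated genes and exons
are deleted, usually at unequal rates among the three copies, so that one
copy stays least fractionated (LF) and the other two (MF1, MF2) lose more.
The package provides the entire comparative tool chain at desk scale: a
forward simulator of the triplicated region evolving along the species
tree `(((A,C),B), outgroup)`, an in-silico BAC library with restriction
fingerprints and probe screens, a Sulston-score physical-map assembler,
ortholog detection with collinearity chaining and inversion calls, NG86
Ks/Ka estimation with molecular-clock dating, retention statistics, and
Dollo-parsimony attribution of gene losses to tree branches.

## The evolutionary model

The simulator starts from an annotated ancestral region
(`simulate_ancestral_region()`): protein-coding genes on random strands,
each beginning with ATG, ending with a stop, free of internal stops, with
exon lengths that are codon multiples so that exons tile the CDS in frame.
At the WGT node the region is triplicated; the three copies then evolve
independently down the fixed rooted tree

```
(((A : t_ac, C : t_ac) : t_b - t_ac, B : t_b) : t_wgt - t_b, REF)
```

with node ages (defaults) `t_wgt = 11.6`, `t_b = 6.2`, `t_ac = 3.2` Mya,
the setting of the Brassica A/B/C genomes.  `REF` is the unevolved
ancestor and plays the role of the outgroup reference (the Arabidopsis
side of the comparison): it witnesses the ancestral state for Dollo
attribution and supplies the probe/exon queries for homology search.

**Codon substitution.**  Per codon and branch of `t` years, the number of
proposed single-nucleotide changes is Poisson with mean `3 mu t`
(`mu = 1.5e-8` synonymous substitutions/site/year, the standard plant
clock rate).  A proposal is accepted with probability 1 if synonymous,
`omega = 0.15` if nonsynonymous, and 0 if it would create a stop codon.
With uniform proposals over the nine single-nucleotide neighbours, the
accepted synonymous changes per NG86 synonymous site accumulate at rate
`mu` per year, so two tips separated by time `T` have expected `Ks = 2 mu T`
— exactly the clock the dating module inverts.  This was chosen over a
full rate-matrix simulator because it is calibrated by construction and
needs no eigendecomposition; its small biases (stop-adjacent codons carry
slightly more NG86 synonymous sites than the proposal process uses) stay
well inside the 15% recovery tolerance used in the tests.  Non-coding
sequence (introns, spacers) mutates neutrally at `mu` per site per year.

**Fractionation.**  Each exon of each copy is deleted on a branch of
length `b` My with probability `1 - (1 - p k)^b`, where
`p = exon_del_prob_per_branch = 0.05` per My is the base hazard and
`k` is the sub-genome multiplier `(LF, MF1, MF2) = (0.5, 1.0, 1.3)`.
Integrated over the 11.6 My root-to-tip path these defaults give exon
retention of roughly 75% / 55% / 45% for LF / MF1 / MF2 — the range the
published fractionation tables show for such regions.  A gene whose exons
are all deleted disappears from the annotation.  Deletions on the two stem
branches are inherited by all descendant genomes, which is what makes
shared (stem) losses dominate the branch-loss report, as expected when
most fractionation happens soon after polyploidy.

**Structural events.**  Per-branch counts of inversions (default: one on
the A/C stem, mirroring the A/C-lineage-specific inversion), tandem
duplications, foreign-gene insertions (drawn as fresh random genes so they
can never be mistaken for orthologs of the reference set) and TE-like
filler insertions.  An inversion reverse-complements a run of consecutive
genes (default span 5) in one randomly chosen sub-genome copy; on a gene
this amounts to flipping its strand flag, since assembly already lays
minus-strand genes out reverse-complemented.  A tandem duplication copies
the gene together with about 3 kb of spacer, so the two loci are
resolvable under the 2-kb locus-separation rule used by the homology
module.  Every event is logged in the truth record.

## Homology, collinearity, inversions

Ortholog detection replaces a BLAST screen with fixed identity/coverage
thresholds (defaults: 70% identity over at least 50% of the exon), which
are database-size independent and therefore reproducible.  The seeded
search finds exact 11-mer seeds (both strands), groups them into candidate
loci separated by more than 2 kb, and aligns exactly (Smith–Waterman,
match +1, mismatch −1, gap of length L costing 2 + L) inside a window
around each locus — so its score is a lower bound on the optimal local
score, with equality whenever the optimal alignment contains an 11-mer
exact seed.  Separated loci are reported independently, which is how
tandem duplications surface as two loci of one gene.

Collinear blocks are maximum-weight chains (longest-increasing-subsequence
dynamic programming, hit scores as weights) over hits ordered by reference
position, with target positions strictly increasing (forward) or
decreasing (inverted).  Chains are strand-homogeneous: a collinear block
preserves orientation and an inverted block flips it, and without this
constraint a genome-wide forward chain can steal single hits out of an
inverted block.  Inversion calls merge inverted chains unless a multi-hit
forward chain occupies the reference interval between them, and require at
least two distinct genes.  Maximal exact matches for dotplots are found by
merging runs of shared k-mers along diagonals (k equals the minimum
reported length, so every reportable MEM is recovered exactly).

## Ks, Ka and dating

`codon_align()` trims terminal stops, aligns the translated proteins
globally (Needleman–Wunsch, BLOSUM62, gap opening 10, extension 1),
back-translates and drops every column containing a gap.
`estimate_ks_ka()` implements Nei–Gojobori (1986): synonymous site counts
per codon position exclude mutations to stop codons from the denominator;
multi-nucleotide codon differences are averaged over all orderings of the
changed positions, excluding orderings that pass through a stop (unless
all do); the proportions are Jukes–Cantor corrected,
`d = -(3/4) log(1 - (4/3) p)`, and estimates with `p >= 3/4` are flagged
saturated rather than raising an error.  NG86 with Jukes–Cantor was chosen
over maximum-likelihood pairwise estimation because every quantity is
exactly specifiable and testable against explicit enumeration; it is a
small-Ks-regime approximation and is documented as such.

Dating inverts the strict clock, `T = Ks / (2 mu)` reported in Mya.  When
region pairs are summarised, per-gene times are computed first and then
averaged (mean and population standard deviation).  The alternative —
converting the rounded mean Ks — cannot reproduce time tables whose mean
times carry more precision than the rounded mean Ks they sit next to, so
the per-gene order is used and the ambiguity noted here.

Because fractionation removes whole exons, two ortholog copies may retain
different exon subsets; `pairwise_ks()` therefore restricts both CDS
extractions to the exons retained in *both* copies (exon lengths are codon
multiples, so any subset stays in frame).  Without this, pairs with
disjoint retained exons would force an alignment of non-homologous
sequence and inflate Ks badly.

## Retention statistics and rounding

All report arithmetic is exact ratios with fixed rounding: percentages and
gene densities (bp per annotated gene) round half-away-from-zero at 2
decimal places; the 1-decimal clone-count ratios (fold coverage,
empty-clone rate, probe redundancy) round half-toward-zero.  This split is
what reproduces every printed cell of the published tables the package
bundles (including a redundancy of 35/4 printed as 8.7, which half-up
cannot produce).  Despite the header "gene density (gene/bp)" in the
original table, the printed values are bp per gene (e.g. 311929/72 =
4332.35), and that is what `gene_density()` computes.

"Predicted genes" are operationalised as full-model presence — all
reference exons retained and an annotated model present — switchable to
annotation-only, since the original criterion is in unavailable
supplementary material.

## Dollo loss attribution

A gene (or exon) copy present in the outgroup is ancestrally present; its
presence/absence pattern across A, B and C is explained by the minimum
set of branch losses with no regain (Dollo).  On this topology the minimal
placements are closed-form: all absent maps to the shared stem; A and C
absent (B present) to the A/C stem; a single absence to that terminal; and
the homoplasic patterns (A and B absent with C present, or the mirror)
cost two terminal losses because A and B are not a clade — a stem loss
plus regain is disallowed.  The implementation is verified against an
exhaustive enumeration of all 32 loss placements for all 8 patterns.
Attribution defaults to the genic-region level (a copy is present when at
least one exon is retained); exon-level attribution is a flag away.

## Fingerprint physical map

Clone fingerprints are the HindIII fragment lengths of each insert
(`A^AGCTT`, cut offset fixed at +1 and conserved fragment-length totals).
Band matching is greedy one-to-one in ascending size order with tolerance
3.0 migration units.  The overlap score is the standard binomial Sulston
formulation with per-band chance probability
`p = 1 - (1 - 2 tol / G)^nH` on a gel length `G = 1180` (a 20–1200
capillary sizing window).  Assembly proceeds stepwise from cutoff 1e-35 to
1e-15 in factors of 1e5.  At each cutoff, groups agglomerate by single
linkage — but a merge is rejected if the merged contig would exceed the
10% questionable-clone (Q) fraction, where a clone is Q when the median of
its scores to contig-mates exceeds `cutoff * 1e3`; contigs that still
exceed the fraction are re-split at a 100-fold stricter cutoff (the DQer
step).  Constraining the merges is what gives the DQer teeth: an
unconstrained final single-linkage pass would immediately re-create every
Q-heavy chain it had broken.  The resulting maps are deliberately
conservative — near-perfect co-assembly precision at modest recall — which
is the regime a physical map needs before clones are sequenced.  This is a
simplified, testable stand-in for FPC: the consensus-band map algorithm,
multi-enzyme dye channels and FPC's internal Q criterion are not
reproduced.

## What the simulator does and does not emulate

It emulates: triplication followed by biased exon-level fractionation;
clock-like synonymous divergence at the stated node ages; inversions,
tandem duplications, foreign-gene and TE-like insertions; a BAC library
with realistic insert sizes, empty clones, restriction fingerprints and
probe hybridisation with redundancy.  It does not emulate: TE sequence
realism (fillers are random DNA), recombination, intron length evolution,
codon-usage bias, indels within exons, heterozygosity (the study material
is a doubled haploid), or sequencing/assembly error.  Passing recovery
tests therefore demonstrate that the analysis chain inverts the generative
model faithfully at these scales — not that it would be unbiased on real
reads or real repeat structure.

## Numerical and scale choices

Coordinates are 1-based inclusive throughout (the R/Bioconductor
convention; GFF3 I/O is therefore conversion-free and the round-trip is
identity on intervals).  Ties in sub-genome ranking break by genic-region
retention, then lexicographic copy id; ties in chaining prefer forward
orientation, then smaller target start.  The binomial tail underflows
gracefully (scores far below 1e-35 are representable in double
precision).  Degenerate inputs are contracts, not crashes: empty FASTA
reads warn, probes without retained loci return zeros, all-singleton
assemblies report undefined precision as 1 with a flag, saturated Ks
estimates are flagged and excluded from summaries.

Test and acceptance problem sizes were chosen so the whole suite runs on a
single CPU in minutes: 100-gene regions for divergence and ranking
recovery (200 ranking replicates), a 15-gene region for inversion
recovery, and a 10x library of 154 clones of 130 kb over a 2 Mb sequence
for the physical map.  At these sizes the Monte-Carlo error of every
recovered quantity is several times smaller than the tolerance it is
tested against.

## Known limitations

NG86/JC underestimates at high divergence and carries no among-site rate
variation; dating inherits every caveat of a strict clock.  The homology
thresholds are a stated stand-in for the original E-value criterion.  The
assembler is not FPC and its contigs are not comparable clone-for-clone
with a real FPC map.  Foreign-gene and TE insertions are tags, not
sequence models.  The species tree is fixed at three ingroup taxa plus an
outgroup; larger trees are out of scope.
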