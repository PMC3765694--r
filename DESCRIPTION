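Package: hexafrac
Title: Simulation and Comparative Analysis of Paleohexaploid Genome
    Fractionation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools to study gene fractionation after a whole-genome
    triplication in Brassica-like genomes.  Provides a forward simulator
    of a triplicated ancestral region evolving along the (((A,C),B),
    outgroup) species tree with clock-like codon substitution, biased
    exon deletion and structural rearrangement; in-silico BAC libraries
    with HindIII fingerprints and probe screens; Sulston-score
    fingerprint contig assembly; ortholog detection, collinearity
    chaining, inversion calls and maximal-exact-match dotplots;
    Nei-Gojobori (1986) Ks/Ka estimation with Jukes-Cantor correction
    and molecular-clock divergence dating; retention statistics and
    Dollo-parsimony attribution of gene losses to tree branches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    data.table,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
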