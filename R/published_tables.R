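# Published report tables bundled as plain-text inputs: the probe-screen
# summary, the per-contig fractionation counts, and the pairwise divergence
# table for the six homologous Brassica contigs.  These are inputs for the
# arithmetic checks, not outputs of this package.

published_path <- function(file) {
  p <- system.file("extdata", file, package = "hexafrac")
  if (p == "") stop("bundled table not found: ", file)
  p
}

#' Published probe-screen table
#'
#' Positive-clone and locus counts for the 17 gene-specific probes used to
#' screen the B-genome BAC library, with the redundancy values as printed.
#'
#' @return data frame: `probe`, `n_positive`, `n_loci`,
#'   `printed_redundancy`.
#' @export
published_probe_screen <- function() {
  utils::read.delim(published_path("probe_screen_published.tsv"),
                    stringsAsFactors = FALSE)
}

#' Published fractionation table
#'
#' Per-contig, per-genome retention counts (exons, genic regions, predicted
#' genes), region sizes, TE counts and annotated gene counts for the six
#' triplicated regions, with the printed percentages and gene densities.
#'
#' @return data frame, one row per (contig, genome).
#' @export
published_fractionation <- function() {
  utils::read.delim(published_path("fractionation_published.tsv"),
                    stringsAsFactors = FALSE)
}

#' Published pairwise divergence table
#'
#' Mean Ks and divergence times (Mya) for each region pair of the six
#' contigs (B vs A, B vs C, A vs C and each genome vs the Arabidopsis
#' reference).
#'
#' @return data frame: `contig`, `pair`, `n_genes`, `mean_ks`, `sd_ks`,
#'   `mean_mya`, `sd_mya`.
#' @export
published_divergence <- function() {
  utils::read.delim(published_path("divergence_published.tsv"),
                    stringsAsFactors = FALSE)
}

#' Published BAC library description
#'
#' Clone count, mean insert size, genome size and the empty-clone assay of
#' the B-genome BAC library.
#'
#' @return list: `n_clones`, `insert_mean_bp`, `genome_size_bp`,
#'   `n_empty`, `n_tested`.
#' @export
published_library <- function() {
  list(n_clones = 85248L, insert_mean_bp = 130000L,
       genome_size_bp = 632e6, n_empty = 141L, n_tested = 7680L)
}
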