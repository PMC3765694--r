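# Library, probe-redundancy and fractionation arithmetic.  These are the
# report statistics: each is an exact ratio with a fixed rounding convention
# (1 dp half-down for clone-count ratios, 2 dp half-up for percentages and
# densities).

#' Fold coverage of a clone library
#'
#' `n_clones * mean_insert_bp / genome_size_bp`, reported at 1 dp.
#'
#' @param n_clones number of clones in the library.
#' @param mean_insert_bp mean insert size in bp.
#' @param genome_size_bp genome size in bp.
#' @return fold coverage, rounded to 1 dp.
#' @export
#' @examples
#' library_coverage(85248, 130000, 632e6)  # 17.5
library_coverage <- function(n_clones, mean_insert_bp, genome_size_bp) {
  n_clones <- as.numeric(n_clones)            # clone x insert products
  mean_insert_bp <- as.numeric(mean_insert_bp)  # overflow 32-bit integers
  stopifnot(all(n_clones >= 0), all(mean_insert_bp > 0))
  if (any(genome_size_bp <= 0)) stop("genome_size_bp must be > 0")
  round_half_down(n_clones * mean_insert_bp / genome_size_bp, 1)
}

#' Empty-clone rate of a library
#'
#' `100 * n_empty / n_tested`, reported at 1 dp.
#'
#' @param n_empty number of empty clones observed.
#' @param n_tested number of clones tested.
#' @return percentage of empty clones, rounded to 1 dp.
#' @export
#' @examples
#' empty_clone_rate(141, 7680)  # 1.8
empty_clone_rate <- function(n_empty, n_tested) {
  if (any(n_tested <= 0)) stop("n_tested must be > 0")
  stopifnot(all(n_empty >= 0), all(n_empty <= n_tested))
  round_half_down(100 * n_empty / n_tested, 1)
}

#' Mean redundancy of a hybridisation probe
#'
#' Positive clones per homologous locus, `n_positive / n_loci` at 1 dp.
#'
#' @param n_positive number of clones positive for the probe.
#' @param n_loci number of distinct homologous loci the probe detects.
#' @return mean redundancy, rounded to 1 dp.
#' @export
#' @examples
#' mean_redundancy(35, 4)  # 8.7
#' mean_redundancy(10, 3)  # 3.3
mean_redundancy <- function(n_positive, n_loci) {
  if (any(n_loci < 1)) stop("n_loci must be >= 1")
  stopifnot(all(n_positive >= 0))
  round_half_down(n_positive / n_loci, 1)
}

#' Retention percentage
#'
#' `100 * n_retained / n_total` at 2 dp; used for retained exons, retained
#' genic regions and predicted genes relative to the reference totals.
#'
#' @param n_retained number of retained features.
#' @param n_total reference total (must be positive).
#' @return percentage, rounded to 2 dp.
#' @export
#' @examples
#' retention_pct(207, 388)  # 53.35
#' retention_pct(336, 456)  # 73.68
retention_pct <- function(n_retained, n_total) {
  if (any(n_total <= 0)) stop("n_total must be > 0")
  stopifnot(all(n_retained >= 0), all(n_retained <= n_total))
  round_half_up(100 * n_retained / n_total, 2)
}

#' Gene density of a region
#'
#' Base pairs per annotated gene, `size_bp / n_genes` at 2 dp.
#'
#' @param size_bp region size in bp.
#' @param n_genes number of annotated (ab initio) genes, `>= 1`.
#' @return bp per gene, rounded to 2 dp.
#' @export
#' @examples
#' gene_density(311929, 72)  # 4332.35
gene_density <- function(size_bp, n_genes) {
  if (any(n_genes < 1)) stop("n_genes must be >= 1")
  stopifnot(all(size_bp >= 0))
  round_half_up(size_bp / n_genes, 2)
}

#' Per-region fractionation statistics
#'
#' Assembles the per-copy row of a fractionation report from a presence
#' matrix and the copy's annotation: retained exon / genic-region /
#' predicted-gene counts and percentages against the reference totals, the
#' region size, TE counts, annotated gene count and gene density.
#'
#' A gene counts as a retained genic region when at least one of its exons
#' is retained; as a "predicted gene" when (mode `"full_model"`, the
#' default) all its reference exons are retained and the copy carries an
#' annotated model for it, or (mode `"annotated"`) when it is annotated at
#' all.
#'
#' @param matrix a [build_presence_matrix()] result.
#' @param copy a `genome_copy` (the column of `matrix` to summarise is taken
#'   from its `genome`/`copy` labels).
#' @param predicted_mode `"full_model"` or `"annotated"`.
#' @return list of class `region_stats`.
#' @export
region_stats <- function(matrix, copy, predicted_mode = c("full_model", "annotated")) {
  predicted_mode <- match.arg(predicted_mode)
  stopifnot(inherits(matrix, "presence_matrix"), inherits(copy, "genome_copy"))
  col <- paste0(copy$genome, "_", copy$copy)
  if (!col %in% colnames(matrix$retained)) {
    stop("presence matrix has no column for copy ", col)
  }
  ret <- matrix$retained[, col]
  genes <- matrix$rows$gene
  n_exons_total <- nrow(matrix$rows)
  n_genes_total <- length(unique(genes))
  exon_ret <- sum(ret)
  genic_by_gene <- tapply(ret, genes, any)
  full_by_gene <- tapply(ret, genes, all)
  genic_ret <- sum(genic_by_gene)
  ann <- copy$genes
  ann_anc <- ann$ancestral_id[!is.na(ann$ancestral_id)]
  pred_by_gene <- if (predicted_mode == "full_model") {
    full_by_gene & (names(full_by_gene) %in% ann_anc)
  } else {
    names(genic_by_gene) %in% ann_anc
  }
  pred <- sum(pred_by_gene)
  size_bp <- nchar(copy$sequence)
  n_ab_initio <- nrow(ann)
  out <- list(
    region = paste(copy$genome, copy$copy, sep = "_"),
    genome = copy$genome, copy = copy$copy,
    size_bp = size_bp,
    n_potential_TEs = length(copy$tes$start),
    retained_exons = exon_ret,
    retained_exons_pct = retention_pct(exon_ret, n_exons_total),
    retained_genic = genic_ret,
    retained_genic_pct = retention_pct(genic_ret, n_genes_total),
    predicted_genes = pred,
    predicted_genes_pct = retention_pct(pred, n_genes_total),
    n_ab_initio_genes = n_ab_initio,
    gene_density_bp_per_gene = if (n_ab_initio >= 1) gene_density(size_bp, n_ab_initio) else NA_real_,
    ref_exon_total = n_exons_total,
    ref_gene_total = n_genes_total
  )
  class(out) <- "region_stats"
  out
}

#' @export
print.region_stats <- function(x, ...) {
  cat(sprintf(
    "region %s: %d bp, exons %d (%.2f%%), genic %d (%.2f%%), predicted %d (%.2f%%), %d genes, %.2f bp/gene\n",
    x$region, x$size_bp, x$retained_exons, x$retained_exons_pct,
    x$retained_genic, x$retained_genic_pct, x$predicted_genes,
    x$predicted_genes_pct, x$n_ab_initio_genes, x$gene_density_bp_per_gene))
  invisible(x)
}
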