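# The exon x genome-copy retention table: the substrate of all
# fractionation and loss statistics.

#' Build the exon retention (presence) matrix
#'
#' Runs [find_orthologs()] for every copy with open thresholds, records the
#' best identity and coverage per reference exon and copy, and flags an
#' exon as retained when both `min_id` and `min_cov` are met.  Because the
#' thresholds are applied to stored best-hit values, the matrix is monotone
#' in them: raising `min_id` or `min_cov` never adds a retained cell.
#'
#' @param ref the reference `genome_copy`.
#' @param copies named list of target `genome_copy` objects.
#' @param min_id,min_cov retention thresholds (default 70 percent identity
#'   over half the exon).
#' @param hits optional precomputed named list of [find_orthologs()] data
#'   frames (one per copy, thresholds 0) to avoid re-alignment.
#' @param ... passed to [find_orthologs()].
#' @return list of class `presence_matrix`: `rows` (data frame `gene`,
#'   `exon`), `retained` / `identity` / `coverage` matrices (rows x
#'   copies), `hits`, `min_id`, `min_cov`.
#' @export
build_presence_matrix <- function(ref, copies, min_id = 70, min_cov = 0.5,
                                  hits = NULL, ...) {
  stopifnot(inherits(ref, "genome_copy"), length(copies) >= 1,
            all(vapply(copies, inherits, TRUE, "genome_copy")))
  ex <- ref$exons[order(ref$exons$start), , drop = FALSE]
  rows <- data.frame(gene = ex$gene_id, exon = ex$anc_index,
                     stringsAsFactors = FALSE)
  labs <- vapply(copies, function(cp) paste(cp$genome, cp$copy, sep = "_"), "")
  n <- nrow(rows)
  mk <- function(x) matrix(x, n, length(labs), dimnames = list(NULL, labs))
  identity <- mk(NA_real_)
  coverage <- mk(NA_real_)
  if (is.null(hits)) {
    hits <- lapply(copies, function(cp)
      find_orthologs(ref, cp, min_id = 0, min_cov = 0, ...))
  }
  names(hits) <- labs
  key_rows <- paste(rows$gene, rows$exon)
  for (lab in labs) {
    h <- hits[[lab]]
    if (!nrow(h)) next
    h <- h[order(-h$score), , drop = FALSE]
    h <- h[!duplicated(paste(h$gene, h$exon)), , drop = FALSE]
    ri <- match(paste(h$gene, h$exon), key_rows)
    ok <- !is.na(ri)
    identity[ri[ok], lab] <- h$identity[ok]
    coverage[ri[ok], lab] <- h$coverage[ok]
  }
  retained <- !is.na(identity) & identity >= min_id &
    !is.na(coverage) & coverage >= min_cov
  out <- list(rows = rows, retained = retained, identity = identity,
              coverage = coverage, hits = hits,
              min_id = min_id, min_cov = min_cov)
  class(out) <- "presence_matrix"
  out
}

#' Re-threshold an existing presence matrix
#'
#' Recomputes the retained flags from the stored best-hit identities and
#' coverages without re-running any alignment.
#'
#' @param matrix a [build_presence_matrix()] result.
#' @param min_id,min_cov new thresholds.
#' @return an updated `presence_matrix`.
#' @export
rethreshold_presence <- function(matrix, min_id, min_cov) {
  stopifnot(inherits(matrix, "presence_matrix"))
  matrix$retained <- !is.na(matrix$identity) & matrix$identity >= min_id &
    !is.na(matrix$coverage) & matrix$coverage >= min_cov
  matrix$min_id <- min_id
  matrix$min_cov <- min_cov
  matrix
}

#' Presence matrix taken directly from simulator truth
#'
#' Bypasses sequence alignment: an exon is retained in a copy exactly when
#' the copy's annotation still carries it.  Used for loss-attribution and
#' ranking studies where the question is about the retention pattern, not
#' about ortholog detection.
#'
#' @param ref the ancestral `genome_copy`.
#' @param copies named list of evolved `genome_copy` objects.
#' @return a `presence_matrix` (identity/coverage are 100/1 where retained).
#' @export
presence_from_annotation <- function(ref, copies) {
  stopifnot(inherits(ref, "genome_copy"))
  ex <- ref$exons[order(ref$exons$start), , drop = FALSE]
  rows <- data.frame(gene = ex$gene_id, exon = ex$anc_index,
                     stringsAsFactors = FALSE)
  labs <- vapply(copies, function(cp) paste(cp$genome, cp$copy, sep = "_"), "")
  ret <- matrix(FALSE, nrow(rows), length(labs), dimnames = list(NULL, labs))
  key_rows <- paste(rows$gene, rows$exon)
  for (i in seq_along(copies)) {
    cp <- copies[[i]]
    anc_of <- stats::setNames(cp$genes$ancestral_id, cp$genes$id)
    anc_gene <- anc_of[cp$exons$gene_id]
    keep <- !is.na(anc_gene)
    ri <- match(paste(anc_gene[keep], cp$exons$anc_index[keep]), key_rows)
    ret[ri[!is.na(ri)], labs[i]] <- TRUE
  }
  out <- list(rows = rows, retained = ret,
              identity = ifelse(ret, 100, NA_real_),
              coverage = ifelse(ret, 1, NA_real_),
              hits = NULL, min_id = NA_real_, min_cov = NA_real_)
  class(out) <- "presence_matrix"
  out
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d exon rows x %d copies, %.1f%% retained\n",
              nrow(x$rows), ncol(x$retained), 100 * mean(x$retained)))
  invisible(x)
}
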