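# Dollo-parsimony attribution of gene losses to branches of the fixed
# species tree (((A,C),B),REF) and sub-genome ranking.

#' The fixed species tree used for loss attribution
#'
#' Rooted topology `(((A,C),B),REF)` with the outgroup REF carrying the
#' ancestral (pre-triplication) state.  Branches are identified as
#' `stem_ABC` (root to the A/B/C ancestor), `stem_AC`, and the three
#' terminals.  The outgroup is never assigned losses.
#'
#' @return list of class `species_tree` with `branches` and `tip_paths`
#'   (root-to-tip branch sets per ingroup tip).
#' @export
species_tree <- function() {
  out <- list(
    branches = c("stem_ABC", "stem_AC", "term_A", "term_B", "term_C"),
    tip_paths = list(
      A = c("stem_ABC", "stem_AC", "term_A"),
      B = c("stem_ABC", "term_B"),
      C = c("stem_ABC", "stem_AC", "term_C")
    )
  )
  class(out) <- "species_tree"
  out
}

#' Dollo-parsimony loss placement for one presence pattern
#'
#' Given presence/absence of one ancestral gene (or exon) copy in the A, B
#' and C genomes — the gene being ancestrally present, as witnessed by the
#' outgroup — returns the minimum set of branch losses explaining the
#' pattern under Dollo parsimony (no regain).  A loss on a branch removes
#' the gene from every tip below it, so a tip is present iff no branch on
#' its root path carries a loss.
#'
#' The minimal placements on this topology: all absent -> `stem_ABC`; A and
#' C absent, B present -> `stem_AC`; exactly one absent -> that terminal;
#' A and B absent, C present (and its mirror) is homoplasic — A and B do not
#' form a clade — and costs two terminal losses.
#'
#' @param present named logical vector with elements `A`, `B`, `C`.
#' @param tree a [species_tree()] (present for interface symmetry).
#' @return character vector of branch ids carrying a loss (possibly empty).
#' @export
#' @examples
#' dollo_assign(c(A = FALSE, B = FALSE, C = FALSE))  # "stem_ABC"
#' dollo_assign(c(A = FALSE, B = TRUE, C = FALSE))   # "stem_AC"
#' dollo_assign(c(A = FALSE, B = FALSE, C = TRUE))   # term_A, term_B
dollo_assign <- function(present, tree = species_tree()) {
  stopifnot(is.logical(present), all(c("A", "B", "C") %in% names(present)))
  a <- present[["A"]]; b <- present[["B"]]; cc <- present[["C"]]
  if (!a && !b && !cc) return("stem_ABC")
  losses <- character(0)
  if (!a && !cc) {
    losses <- c(losses, "stem_AC")
  } else {
    if (!a) losses <- c(losses, "term_A")
    if (!cc) losses <- c(losses, "term_C")
  }
  if (!b) losses <- c(losses, "term_B")
  intersect(tree$branches, losses)  # canonical order
}

#' Per-branch fractionation report from a presence matrix
#'
#' Rolls the exon-level presence matrix up to genic regions (a gene copy is
#' present in a genome when at least one exon is retained; set
#' `unit = "exon"` to attribute at exon level instead), applies
#' [dollo_assign()] per ancestral gene and sub-genome copy, and tallies loss
#' counts and percentages (of the reference gene total) per branch and copy.
#' Homoplasic patterns — those whose Dollo cost exceeds one — are listed in
#' the `homoplasic` element.
#'
#' @param matrix a [build_presence_matrix()] result covering all three
#'   genomes for each sub-genome copy.
#' @param tree a [species_tree()].
#' @param unit `"gene"` (default) or `"exon"`.
#' @return list of class `branch_loss_report`: `counts` and `pct` matrices
#'   (branch x copy), `n_units`, `homoplasic` data frame.
#' @export
branch_fractionation <- function(matrix, tree = species_tree(), unit = c("gene", "exon")) {
  unit <- match.arg(unit)
  stopifnot(inherits(matrix, "presence_matrix"))
  copies <- unique(sub("^[ABC]_", "", grep("^[ABC]_", colnames(matrix$retained), value = TRUE)))
  genomes <- c("A", "B", "C")
  need <- as.vector(outer(genomes, copies, paste, sep = "_"))
  missing <- setdiff(need, colnames(matrix$retained))
  if (length(missing)) stop("presence matrix incomplete; missing: ",
                            paste(missing, collapse = ", "))
  if (unit == "gene") {
    genes <- matrix$rows$gene
    pres <- sapply(need, function(cl) tapply(matrix$retained[, cl], genes, any))
    units <- rownames(pres)
  } else {
    pres <- matrix$retained[, need, drop = FALSE]
    units <- paste(matrix$rows$gene, matrix$rows$exon, sep = ":")
    rownames(pres) <- NULL
  }
  counts <- matrix(0L, length(tree$branches), length(copies),
                   dimnames = list(tree$branches, copies))
  homo <- list()
  for (cp in copies) {
    for (u in seq_len(NROW(pres))) {
      pat <- c(A = unname(pres[u, paste0("A_", cp)]),
               B = unname(pres[u, paste0("B_", cp)]),
               C = unname(pres[u, paste0("C_", cp)]))
      ev <- dollo_assign(pat, tree)
      for (b in ev) counts[b, cp] <- counts[b, cp] + 1L
      if (length(ev) > 1L) {
        homo[[length(homo) + 1L]] <- data.frame(
          unit = units[u], copy = cp,
          pattern = paste(as.integer(pat), collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  n_units <- NROW(pres)
  out <- list(
    counts = counts,
    pct = round_half_up(100 * counts / n_units, 2),
    n_units = n_units,
    unit = unit,
    homoplasic = if (length(homo)) do.call(rbind, homo) else
      data.frame(unit = character(0), copy = character(0), pattern = character(0))
  )
  class(out) <- "branch_loss_report"
  out
}

#' @export
print.branch_loss_report <- function(x, ...) {
  cat("Branch-partitioned fractionation (", x$unit, " level, n = ",
      x$n_units, ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Rank three sub-genome copies as LF / MF1 / MF2
#'
#' Orders the three copies of one genome by descending retained-exon
#' percentage — least fractionated (LF) first, then MF1, then MF2.  Ties are
#' broken by retained-genic-region percentage, then by copy id
#' (lexicographic), so the output is deterministic.
#'
#' @param stats list of exactly three [region_stats()] objects (the three
#'   copies of one genome).
#' @return named character vector: copy id -> rank label (`LF`, `MF1`,
#'   `MF2`), in rank order.
#' @export
rank_subgenomes <- function(stats) {
  if (length(stats) != 3L) stop("exactly 3 copies are required")
  stopifnot(all(vapply(stats, inherits, TRUE, "region_stats")))
  ids <- vapply(stats, `[[`, "", "copy")
  exon_pct <- vapply(stats, `[[`, 0, "retained_exons_pct")
  genic_pct <- vapply(stats, `[[`, 0, "retained_genic_pct")
  ord <- order(-exon_pct, -genic_pct, ids)
  stats::setNames(c("LF", "MF1", "MF2"), ids[ord])
}
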