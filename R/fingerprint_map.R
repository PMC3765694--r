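# Sulston-score overlap probabilities between clone fingerprints and
# stepwise-stringency contig assembly with DQer-style breaking of
# questionable contigs.

#' Assembly parameters for the fingerprint map
#'
#' @param tolerance band-matching tolerance in migration units (default 3.0).
#' @param gel_length usable sizing range in migration units (default 1180,
#'   a 20-1200 capillary sizing window).
#' @param cutoff_start initial (most stringent) Sulston cutoff (default 1e-35).
#' @param cutoff_end final cutoff (default 1e-15).
#' @param cutoff_step_factor multiplicative step between cutoffs (default 1e5).
#' @param dq_fraction maximum tolerated fraction of questionable (Q) clones
#'   in a contig before it is re-split (default 0.10).
#' @return list of class `assembly_params`.
#' @export
assembly_params <- function(tolerance = 3.0, gel_length = 1180,
                            cutoff_start = 1e-35, cutoff_end = 1e-15,
                            cutoff_step_factor = 1e5, dq_fraction = 0.10) {
  stopifnot(tolerance >= 0, gel_length > 0,
            cutoff_start > 0, cutoff_end < 1, cutoff_start <= cutoff_end,
            cutoff_step_factor > 1 || cutoff_start == cutoff_end,
            dq_fraction > 0, dq_fraction < 1)
  structure(list(tolerance = tolerance, gel_length = gel_length,
                 cutoff_start = cutoff_start, cutoff_end = cutoff_end,
                 cutoff_step_factor = cutoff_step_factor,
                 dq_fraction = dq_fraction),
            class = "assembly_params")
}

#' Count shared bands between two fingerprints
#'
#' Greedy one-to-one pairing in ascending band-size order: walking both
#' sorted band lists, two bands match when their sizes differ by at most
#' `tolerance`, and each band is used at most once.
#'
#' @param fp_a,fp_b numeric vectors of band sizes (sorted internally).
#' @param tolerance matching tolerance.
#' @return integer number of shared bands.
#' @export
#' @examples
#' match_bands(c(100, 104), 102, tolerance = 3)  # 1 (100 pairs with 102)
match_bands <- function(fp_a, fp_b, tolerance = 3.0) {
  stopifnot(is.numeric(fp_a), is.numeric(fp_b), tolerance >= 0)
  a <- sort(fp_a); b <- sort(fp_b)
  i <- 1L; j <- 1L; m <- 0L
  while (i <= length(a) && j <= length(b)) {
    d <- a[i] - b[j]
    if (abs(d) <= tolerance) {
      m <- m + 1L; i <- i + 1L; j <- j + 1L
    } else if (d < 0) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  m
}

#' Sulston overlap score between two fingerprints
#'
#' Probability that two unrelated fingerprints would share at least the
#' observed number of bands by chance.  With `nL`/`nH` the smaller/larger
#' band count, `m` the shared-band count from [match_bands()], and
#' per-band chance-match probability
#' `p = 1 - (1 - 2 tolerance / gel_length)^nH`, the score is the binomial
#' tail `sum_{j=m}^{nL} C(nL, j) p^j (1-p)^(nL-j)`.  Lower scores indicate
#' stronger evidence of true overlap; `m = 0` gives 1.
#'
#' @inheritParams match_bands
#' @param gel_length usable sizing range (migration units).
#' @return the overlap probability in `(0, 1]`.
#' @export
sulston_score <- function(fp_a, fp_b, tolerance = 3.0, gel_length = 1180) {
  stopifnot(length(fp_a) >= 1, length(fp_b) >= 1)
  if (tolerance >= gel_length / 2) stop("tolerance must be < gel_length / 2")
  nL <- min(length(fp_a), length(fp_b))
  nH <- max(length(fp_a), length(fp_b))
  m <- match_bands(fp_a, fp_b, tolerance)
  p <- 1 - (1 - 2 * tolerance / gel_length)^nH
  if (m == 0L) return(1)
  sum(stats::dbinom(m:nL, nL, p))
}

# Internal: full symmetric score matrix for a fingerprint list.
sulston_matrix <- function(fingerprints, params) {
  n <- length(fingerprints)
  s <- matrix(1, n, n)
  if (n < 2L) return(s)
  for (i in seq_len(n - 1L)) {
    fa <- fingerprints[[i]]
    if (length(fa) == 0L) next
    for (j in (i + 1L):n) {
      fb <- fingerprints[[j]]
      if (length(fb) == 0L) next
      s[i, j] <- s[j, i] <- sulston_score(fa, fb, params$tolerance, params$gel_length)
    }
  }
  s
}

# Internal: Q flags for a group — a clone is questionable when the median
# of its Sulston scores to contig-mates exceeds cutoff * 1e3.
q_flags <- function(g, scores, cutoff) {
  if (length(g) < 2L) return(rep(FALSE, length(g)))
  vapply(g, function(i) {
    stats::median(scores[i, setdiff(g, i)]) > cutoff * 1e3
  }, TRUE)
}

# Internal: agglomerative single linkage constrained by the Q criterion —
# candidate group pairs (best inter-group score <= cutoff) are merged in
# ascending score order, but a merge whose result would exceed the DQer
# Q-fraction threshold is rejected; repeats until no acceptable merge
# remains.  Deterministic.
q_constrained_merge <- function(groups, scores, cutoff, params) {
  repeat {
    ng <- length(groups)
    if (ng < 2L) return(groups)
    best <- NULL
    for (i in seq_len(ng - 1L)) {
      for (j in (i + 1L):ng) {
        s <- min(scores[groups[[i]], groups[[j]]])
        if (s > cutoff) next
        if (!is.null(best) && s >= best$s) next
        merged <- c(groups[[i]], groups[[j]])
        if (mean(q_flags(merged, scores, cutoff)) > params$dq_fraction) next
        best <- list(i = i, j = j, s = s)
      }
    }
    if (is.null(best)) return(groups)
    groups[[best$i]] <- sort(c(groups[[best$i]], groups[[best$j]]))
    groups[[best$j]] <- NULL
  }
}

# Internal: partition clone indices into single-linkage components under a
# score cutoff, optionally restricted to a subset.
sl_components <- function(scores, cutoff, subset = seq_len(nrow(scores))) {
  n <- length(subset)
  if (n == 0L) return(list())
  sub <- scores[subset, subset, drop = FALSE]
  adj <- sub <= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  lapply(split(seq_len(n), comp), function(ix) subset[ix])
}

#' Stepwise-stringency contig assembly of clone fingerprints
#'
#' FPC-style stepwise assembly: starting at `cutoff_start` and relaxing by
#' `cutoff_step_factor` until `cutoff_end`, groups are agglomerated by
#' single linkage over pairs whose Sulston score is at or below the current
#' cutoff.  After each agglomeration a clone is flagged questionable (Q)
#' when the median of its scores to contig-mates exceeds `cutoff * 1e3`, and
#' any contig whose Q fraction exceeds `dq_fraction` is re-split at a
#' 100-fold stricter cutoff (the DQer step).  Empty fingerprints are kept as
#' singletons.  Deterministic for a given input.
#'
#' @param fingerprints named list of numeric band-size vectors (names are
#'   clone ids; unnamed input gets `clone1..cloneN`).
#' @param params an [assembly_params()].
#' @return list of class `contig_set`: `contigs` (list of clone-id vectors,
#'   each of size >= 2), `singletons`, `q_clones`, `q_fraction` per contig,
#'   and the score matrix used.
#' @export
assemble_stepwise <- function(fingerprints, params = assembly_params()) {
  stopifnot(is.list(fingerprints), length(fingerprints) >= 1)
  if (is.null(names(fingerprints))) {
    names(fingerprints) <- paste0("clone", seq_along(fingerprints))
  }
  ids <- names(fingerprints)
  n <- length(fingerprints)
  scores <- sulston_matrix(fingerprints, params)
  cutoffs <- params$cutoff_start
  while (utils::tail(cutoffs, 1) * params$cutoff_step_factor <= params$cutoff_end) {
    cutoffs <- c(cutoffs, utils::tail(cutoffs, 1) * params$cutoff_step_factor)
  }
  if (utils::tail(cutoffs, 1) < params$cutoff_end) {
    cutoffs <- c(cutoffs, params$cutoff_end)
  }
  groups <- as.list(seq_len(n))
  q_flag <- rep(FALSE, n)
  for (cutoff in cutoffs) {
    groups <- q_constrained_merge(groups, scores, cutoff, params)
    # DQer: re-split any contig whose Q fraction exceeds the threshold at a
    # 100-fold stricter cutoff
    next_groups <- list()
    for (g in groups) {
      qg <- q_flags(g, scores, cutoff)
      q_flag[g] <- qg
      if (length(g) >= 2L && mean(qg) > params$dq_fraction) {
        next_groups <- c(next_groups, sl_components(scores, cutoff * 1e-2, g))
      } else {
        next_groups <- c(next_groups, list(g))
      }
    }
    groups <- next_groups
  }
  # final merge pass at the end cutoff (same Q constraint), then split
  # contigs from singletons
  groups <- q_constrained_merge(groups, scores, params$cutoff_end, params)
  for (g in groups) q_flag[g] <- q_flags(g, scores, params$cutoff_end)
  sizes <- lengths(groups)
  contigs <- groups[sizes >= 2L]
  contigs <- contigs[order(-lengths(contigs),
                           vapply(contigs, min, 0L))]
  singles <- sort(unlist(groups[sizes < 2L]))
  qfrac <- vapply(contigs, function(g) mean(q_flag[g]), 0)
  out <- list(
    contigs = stats::setNames(lapply(contigs, function(g) ids[sort(g)]),
                              sprintf("ctg%d", seq_along(contigs))),
    singletons = ids[singles],
    q_clones = ids[q_flag],
    q_fraction = qfrac,
    cutoffs = cutoffs
  )
  class(out) <- "contig_set"
  out
}

#' @export
print.contig_set <- function(x, ...) {
  n <- length(unlist(x$contigs)) + length(x$singletons)
  cat(sprintf("contig_set: %d contigs, %d singletons (%.0f%%) of %d clones\n",
              length(x$contigs), length(x$singletons),
              100 * length(x$singletons) / n, n))
  invisible(x)
}

#' Evaluate a fingerprint assembly against simulated clone positions
#'
#' A clone pair is a true positive when it is co-assembled in one contig and
#' its true genomic intervals overlap by at least `min_overlap_bp`.
#' Precision is TP / co-assembled pairs; recall is TP / truly-overlapping
#' pairs.  With no co-assembled pairs, precision is undefined and reported
#' as 1 with `precision_defined = FALSE`.
#'
#' @param contigs a [assemble_stepwise()] result.
#' @param clone_truth data frame with columns `id`, `start`, `end` (true
#'   genomic interval per clone, 1-based inclusive).
#' @param min_overlap_bp minimum true overlap for a pair to count (default
#'   30000).
#' @return list with `precision`, `recall`, `tp`, `n_assembled_pairs`,
#'   `n_true_pairs`, `precision_defined`.
#' @export
evaluate_assembly <- function(contigs, clone_truth, min_overlap_bp = 30000) {
  stopifnot(inherits(contigs, "contig_set"),
            all(c("id", "start", "end") %in% names(clone_truth)))
  ov <- function(i, j) {
    pmax(0, pmin(clone_truth$end[i], clone_truth$end[j]) -
           pmax(clone_truth$start[i], clone_truth$start[j]) + 1)
  }
  idx <- stats::setNames(seq_len(nrow(clone_truth)), clone_truth$id)
  tp <- 0L; n_asm <- 0L
  for (ctg in contigs$contigs) {
    ii <- idx[ctg]
    if (length(ii) < 2L) next
    prs <- utils::combn(ii, 2L)
    n_asm <- n_asm + ncol(prs)
    tp <- tp + sum(ov(prs[1L, ], prs[2L, ]) >= min_overlap_bp)
  }
  all_pairs <- utils::combn(seq_len(nrow(clone_truth)), 2L)
  n_true <- sum(ov(all_pairs[1L, ], all_pairs[2L, ]) >= min_overlap_bp)
  list(
    precision = if (n_asm > 0L) tp / n_asm else 1,
    recall = if (n_true > 0L) tp / n_true else 0,
    tp = tp, n_assembled_pairs = n_asm, n_true_pairs = n_true,
    precision_defined = n_asm > 0L
  )
}
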