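# Collinearity: maximum-weight monotone chaining of ortholog hits,
# inversion calls from inverted chains, and maximal exact matches (MEMs)
# for dotplots.

# Internal: maximum-weight strictly monotone subsequence of hits (rows of
# `h`, already sorted by ref_pos) with target position increasing
# (direction +1) or decreasing (-1).  Weight is the hit score.  Ties prefer
# smaller target start.  Returns row indices of the best chain.
best_monotone_chain <- function(h, direction) {
  n <- nrow(h)
  if (n == 0L) return(integer(0))
  w <- h$score
  best <- w
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ok <- h$ref_pos[j] < h$ref_pos[i] &&
        sign(h$t_start[i] - h$t_start[j]) == direction
      if (ok && best[j] + w[i] > best[i]) {
        best[i] <- best[j] + w[i]
        prev[i] <- j
      }
    }
  }
  end <- which(best == max(best))
  end <- end[order(h$t_start[end])][1L]
  chain <- integer(0)
  while (!is.na(end)) {
    chain <- c(end, chain)
    end <- prev[end]
  }
  chain
}

#' Chain ortholog hits into collinear blocks
#'
#' Iteratively extracts maximum-weight chains from the hits of one
#' (reference, copy) pair: a chain is a set of hits strictly increasing in
#' reference order whose target coordinates are monotone — increasing for a
#' forward chain, decreasing for an inverted one.  Chains are found by
#' longest-increasing-subsequence dynamic programming with hit scores as
#' weights; at each round the heavier of the best forward and best inverted
#' chain is removed (ties prefer forward, then smaller target start), so
#' every hit is assigned to at most one chain.
#'
#' @param hits a [find_orthologs()] data frame for one copy.
#' @return list of `synteny_chain` objects: `hits` (data frame),
#'   `orientation` (`"forward"`/`"inverted"`), `weight`, `genes`,
#'   `ref_span`, `target_span`.
#' @export
chain_collinear <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (length(unique(hits$copy)) > 1L) stop("hits must come from a single copy")
  chains <- list()
  h <- hits[order(hits$ref_pos, hits$t_start), , drop = FALSE]
  while (nrow(h) > 0L) {
    # candidate chains are strand-homogeneous (a collinear block preserves
    # orientation; an inverted block flips it), in both target directions
    cand <- list()
    for (std in intersect(c("+", "-"), unique(h$strand))) {
      sub_i <- which(h$strand == std)
      for (dir in c(+1, -1)) {
        sel <- sub_i[best_monotone_chain(h[sub_i, , drop = FALSE], dir)]
        cand[[length(cand) + 1L]] <- list(
          sel = sel, weight = sum(h$score[sel]), dir = dir, strand = std,
          t0 = if (length(sel)) min(h$t_start[sel]) else Inf)
      }
    }
    ord <- order(-vapply(cand, `[[`, 0, "weight"),
                 vapply(cand, `[[`, 0, "dir") * -1,
                 vapply(cand, `[[`, 0, "t0"))
    pick <- cand[[ord[1L]]]
    sub <- h[pick$sel, , drop = FALSE]
    chains[[length(chains) + 1L]] <- structure(list(
      hits = sub,
      orientation = if (pick$dir > 0 || nrow(sub) == 1L) "forward" else "inverted",
      weight = sum(sub$score),
      genes = unique(sub$gene),
      ref_span = range(sub$ref_pos),
      target_span = range(c(sub$t_start, sub$t_end))
    ), class = "synteny_chain")
    h <- h[-pick$sel, , drop = FALSE]
  }
  chains[order(-vapply(chains, `[[`, 0, "weight"))]
}

#' @export
print.synteny_chain <- function(x, ...) {
  cat(sprintf("synteny_chain (%s): %d hits, weight %.0f, genes %s\n",
              x$orientation, nrow(x$hits), x$weight,
              paste(x$genes, collapse = ",")))
  invisible(x)
}

#' Call inversions from chained hits
#'
#' Maximal runs of inverted-orientation chains (consecutive along the
#' reference) covering at least `min_genes` distinct genes are reported
#' with their reference and target breakpoint spans.
#'
#' @param chains a [chain_collinear()] result for one copy.
#' @param min_genes minimum distinct genes in a call (default 2).
#' @return data frame: `copy`, `genes`, `n_genes`, `ref_start`, `ref_end`,
#'   `t_start`, `t_end` (empty when there is no inverted chain).
#' @export
detect_inversions <- function(chains, min_genes = 2L) {
  empty <- data.frame(copy = character(0), genes = character(0),
                      n_genes = integer(0), ref_start = integer(0),
                      ref_end = integer(0), t_start = integer(0),
                      t_end = integer(0), stringsAsFactors = FALSE)
  if (!length(chains)) return(empty)
  inv_chains <- Filter(function(ch) ch$orientation == "inverted", chains)
  if (!length(inv_chains)) return(empty)
  fwd_pos <- unlist(lapply(Filter(function(ch) ch$orientation == "forward" &&
                                    nrow(ch$hits) > 1L, chains),
                           function(ch) ch$hits$ref_pos))
  inv_chains <- inv_chains[order(vapply(inv_chains,
                                        function(ch) ch$ref_span[1L], 0))]
  # merge consecutive inverted chains unless a multi-hit forward chain
  # occupies the reference interval between them
  groups <- list(inv_chains[1L])
  for (ch in inv_chains[-1L]) {
    prev <- groups[[length(groups)]]
    prev_end <- max(vapply(prev, function(x) x$ref_span[2L], 0))
    separated <- any(fwd_pos > prev_end & fwd_pos < ch$ref_span[1L])
    if (separated) {
      groups[[length(groups) + 1L]] <- list(ch)
    } else {
      groups[[length(groups)]] <- c(prev, list(ch))
    }
  }
  calls <- list()
  for (grp in groups) {
    genes <- unique(unlist(lapply(grp, `[[`, "genes")))
    if (length(genes) < min_genes) next
    refs <- range(unlist(lapply(grp, `[[`, "ref_span")))
    tg <- range(unlist(lapply(grp, `[[`, "target_span")))
    calls[[length(calls) + 1L]] <- data.frame(
      copy = grp[[1L]]$hits$copy[1L],
      genes = paste(genes, collapse = ","), n_genes = length(genes),
      ref_start = refs[1L], ref_end = refs[2L],
      t_start = tg[1L], t_end = tg[2L], stringsAsFactors = FALSE)
  }
  if (!length(calls)) return(empty)
  do.call(rbind, calls)
}

#' Find maximal exact matches between two sequences
#'
#' All maximal exact matches (MEMs) of length at least `min_len`, on both
#' strands, located by merging runs of shared `min_len`-mers along
#' diagonals: every MEM of length `>= min_len` is a maximal run of
#' consecutive shared `min_len`-mers on one diagonal, so the merged runs
#' are exactly the MEMs (extension past a run end breaks the match by
#' construction).  Output is dotplot-ready.
#'
#' @param seq_a,seq_b DNA strings.
#' @param min_len minimum match length (default 20).
#' @return data frame: `a_start`, `b_start`, `length`, `strand` (`b_start`
#'   is the leftmost coordinate of the match on the original `seq_b` for
#'   both strands).
#' @export
find_mems <- function(seq_a, seq_b, min_len = 20L) {
  seq_a <- check_dna(seq_a, "seq_a")
  seq_b <- check_dna(seq_b, "seq_b")
  k <- as.integer(min_len)
  stopifnot(k >= 2L)
  plus <- mem_plus_strand(seq_a, seq_b, k)
  if (nrow(plus)) plus$strand <- "+"
  brc <- revcomp(seq_b)
  minus <- mem_plus_strand(seq_a, brc, k)
  if (nrow(minus)) {
    minus$b_start <- nchar(seq_b) - (minus$b_start + minus$length - 1L) + 1L
    minus$strand <- "-"
  }
  out <- rbind(plus, minus)
  if (!nrow(out)) {
    return(data.frame(a_start = integer(0), b_start = integer(0),
                      length = integer(0), strand = character(0)))
  }
  rownames(out) <- NULL
  out[order(out$a_start, out$b_start), , drop = FALSE]
}

# Internal: plus-strand MEMs via a data.table k-mer join.
mem_plus_strand <- function(a, b, k) {
  empty <- data.frame(a_start = integer(0), b_start = integer(0),
                      length = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (nchar(a) < k || nchar(b) < k) return(empty)
  kmer_dt <- function(s) {
    starts <- seq_len(nchar(s) - k + 1L)
    data.table::data.table(kmer = substring(s, starts, starts + k - 1L),
                           pos = starts)
  }
  da <- kmer_dt(a)
  db <- kmer_dt(b)
  j <- merge(da, db, by = "kmer", allow.cartesian = TRUE,
             suffixes = c("_a", "_b"))
  if (nrow(j) == 0L) return(empty)
  j[, diag := pos_a - pos_b]
  data.table::setorder(j, diag, pos_a)
  j[, run := cumsum(c(1L, !(diff(pos_a) == 1L & diff(diag) == 0L)))]
  runs <- j[, .(a_start = min(pos_a), b_start = min(pos_b),
                length = max(pos_a) - min(pos_a) + k), by = run]
  as.data.frame(runs[, .(a_start, b_start, length,
                         strand = NA_character_)])
}
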