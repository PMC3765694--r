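# Ortholog detection: local alignment (exact Smith-Waterman and a seeded
# heuristic mode), both-strand search, and locus-aware exon-to-region
# mapping.  Replaces a BLASTN screen with score/identity thresholds that do
# not depend on database size.

default_scoring <- function() {
  list(match = 1, mismatch = -1, gap_open = -2, gap_extend = -1)
}

# Internal: exact local alignment of one oriented query against (a window
# of) the target.  Returns NULL when the best score is <= 0.
sw_hit <- function(query, target, scoring, offset = 0L) {
  subst <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(target),
    type = "local", substitutionMatrix = subst,
    gapOpening = abs(scoring$gap_open), gapExtension = abs(scoring$gap_extend))
  sc <- Biostrings::score(aln)
  if (sc <= 0) return(NULL)
  srange <- Biostrings::subject(aln)
  prange <- Biostrings::pattern(aln)
  alen <- Biostrings::nchar(aln)
  list(
    score = sc,
    identity = 100 * Biostrings::nmatch(aln) / alen,
    coverage = (BiocGenerics::end(prange) - BiocGenerics::start(prange) + 1) /
      nchar(query),
    t_start = BiocGenerics::start(srange) + offset,
    t_end = BiocGenerics::end(srange) + offset
  )
}

# Internal: keyed k-mer position index of a target sequence, built once per
# target and shared across all queries against it.
kmer_index <- function(target, k) {
  if (nchar(target) < k) {
    return(data.table::data.table(kmer = character(0), pos = integer(0),
                                  key = "kmer"))
  }
  starts <- seq_len(nchar(target) - k + 1L)
  dt <- data.table::data.table(kmer = substring(target, starts, starts + k - 1L),
                               pos = starts)
  data.table::setkey(dt, kmer)
  dt
}

# Internal: positions of exact k-mer seed matches of `query` in the indexed
# target (plus strand).  Returns sorted integer target start positions.
seed_positions <- function(query, index, k) {
  n <- nchar(query)
  if (n < k) return(integer(0))
  starts <- seq_len(n - k + 1L)
  kmers <- unique(substring(query, starts, starts + k - 1L))
  hits <- index[data.table::data.table(kmer = kmers), pos, nomatch = NULL]
  sort(unique(hits))
}

# Internal: cluster sorted positions into groups separated by > gap.
cluster_positions <- function(pos, gap) {
  if (!length(pos)) return(list())
  breaks <- c(0L, which(diff(pos) > gap), length(pos))
  lapply(seq_len(length(breaks) - 1L), function(i) {
    pos[(breaks[i] + 1L):breaks[i + 1L]]
  })
}

#' Best local alignment of a query against a target, both strands
#'
#' Scoring is +1 match, -1 mismatch, and an affine gap of length L costs
#' `|gap_open| + L |gap_extend|`.  `mode = "exact_sw"` computes the optimal
#' local (Smith-Waterman) alignment; `mode = "seeded"` finds exact `k`-mer
#' seed matches, opens a window around each seed cluster and aligns exactly
#' within the window — its score is a lower bound on the optimal one, with
#' equality whenever the optimal alignment contains an exact seed of length
#' `>= k`.  Both strands are searched and the better one reported.
#'
#' @param query,target DNA strings.
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @param mode `"exact_sw"` or `"seeded"`.
#' @param k seed length for the seeded mode (default 11).
#' @return `NULL` if no positive-scoring alignment exists, else a list of
#'   class `alignment_hit`: `score`, `identity` (percent), `coverage`
#'   (fraction of query aligned), `t_start`, `t_end` (1-based target
#'   interval), `strand`.
#' @export
align_local <- function(query, target, scoring = default_scoring(),
                        mode = c("exact_sw", "seeded"), k = 11L) {
  mode <- match.arg(mode)
  query <- check_dna(query, "query")
  target <- check_dna(target, "target")
  best <- NULL
  index <- if (mode == "seeded") kmer_index(target, k) else NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    hits <- if (mode == "exact_sw") {
      h <- sw_hit(q, target, scoring)
      if (is.null(h)) list() else list(h)
    } else {
      pos <- seed_positions(q, index, k)
      lapply(cluster_positions(pos, gap = nchar(q) + 2L * k), function(cl) {
        w0 <- max(1L, min(cl) - nchar(q) - k)
        w1 <- min(nchar(target), max(cl) + nchar(q) + 2L * k)
        sw_hit(q, substring(target, w0, w1), scoring, offset = w0 - 1L)
      })
    }
    for (h in hits) {
      if (is.null(h)) next
      h$strand <- strand
      if (is.null(best) || h$score > best$score ||
          (h$score == best$score && best$strand == "-" && strand == "+")) {
        best <- h
      }
    }
  }
  if (!is.null(best)) class(best) <- "alignment_hit"
  best
}

#' Find orthologous loci of reference exons in a genome copy
#'
#' For every reference exon, exact `k`-mer seeds are located in the target
#' copy (both strands), seed clusters separated by more than
#' `max_locus_gap` become candidate loci, and each candidate is aligned
#' exactly within its window.  Per exon the best hit at each locus is kept
#' when it reaches `min_id` percent identity over `min_cov` of the exon;
#' separated loci are reported independently, which is what exposes tandem
#' duplications.  Genes with no surviving homolog are simply absent.
#'
#' @param ref a reference `genome_copy` (the annotated ancestor).
#' @param copy the target `genome_copy`.
#' @param min_id minimum percent identity (default 70).
#' @param min_cov minimum fraction of the exon aligned (default 0.5).
#' @param max_locus_gap target-side gap separating distinct loci (default
#'   2000 bp).
#' @param k seed length (default 11).
#' @param scoring alignment scoring, as in [align_local()].
#' @return data frame of hits: `gene`, `exon`, `copy`, `ref_pos`,
#'   `t_start`, `t_end`, `strand`, `score`, `identity`, `coverage`,
#'   `locus` (per-gene locus index in target order).
#' @export
find_orthologs <- function(ref, copy, min_id = 70, min_cov = 0.5,
                           max_locus_gap = 2000L, k = 11L,
                           scoring = default_scoring()) {
  stopifnot(inherits(ref, "genome_copy"), inherits(copy, "genome_copy"))
  target <- copy$sequence
  index <- kmer_index(target, k)
  lab <- paste(copy$genome, copy$copy, sep = "_")
  ex <- ref$exons[order(ref$exons$start), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(ex))) {
    q <- substring(ref$sequence, ex$start[i], ex$end[i])
    pos <- sort(unique(c(seed_positions(q, index, k),
                         seed_positions(revcomp(q), index, k))))
    for (cl in cluster_positions(pos, gap = max_locus_gap)) {
      w0 <- max(1L, min(cl) - nchar(q) - k)
      w1 <- min(nchar(target), max(cl) + nchar(q) + 2L * k)
      h <- best_window_hit(q, target, w0, w1, scoring)
      if (is.null(h)) next
      if (h$identity < min_id || h$coverage < min_cov) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene = ex$gene_id[i], exon = ex$anc_index[i], copy = lab,
        ref_pos = ex$start[i], t_start = h$t_start, t_end = h$t_end,
        strand = h$strand, score = h$score, identity = h$identity,
        coverage = h$coverage, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(0), exon = integer(0),
                      copy = character(0), ref_pos = integer(0),
                      t_start = integer(0), t_end = integer(0),
                      strand = character(0), score = numeric(0),
                      identity = numeric(0), coverage = numeric(0),
                      locus = integer(0)))
  }
  hits <- do.call(rbind, rows)
  # collapse per-exon duplicate windows (same locus found twice): keep best
  hits <- hits[order(hits$gene, hits$exon, -hits$score, hits$t_start), , drop = FALSE]
  # assign per-gene locus indices by clustering hit positions on the target
  hits$locus <- NA_integer_
  for (g in unique(hits$gene)) {
    gi <- which(hits$gene == g)
    ord <- gi[order(hits$t_start[gi])]
    brk <- c(0L, which(diff(hits$t_start[ord]) > max_locus_gap +
                         stats::median(hits$t_end[ord] - hits$t_start[ord])),
             length(ord))
    for (li in seq_len(length(brk) - 1L)) {
      hits$locus[ord[(brk[li] + 1L):brk[li + 1L]]] <- li
    }
  }
  # best hit per (exon, locus)
  key <- paste(hits$gene, hits$exon, hits$locus)
  hits <- hits[!duplicated(key), , drop = FALSE]
  rownames(hits) <- NULL
  hits[order(hits$ref_pos, hits$locus), , drop = FALSE]
}

# Internal: best oriented hit of q inside target[w0..w1].
best_window_hit <- function(q, target, w0, w1, scoring) {
  win <- substring(target, w0, w1)
  best <- NULL
  for (strand in c("+", "-")) {
    qq <- if (strand == "+") q else revcomp(q)
    h <- sw_hit(qq, win, scoring, offset = w0 - 1L)
    if (is.null(h)) next
    h$strand <- strand
    if (is.null(best) || h$score > best$score) best <- h
  }
  best
}
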