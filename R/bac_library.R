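# In-silico BAC library: clone sampling, HindIII fingerprints, and the
# probe hybridisation screen.

#' BAC library parameters
#'
#' @param n_clones number of clones to draw.
#' @param insert_mean_bp mean insert size (default 130 kb).
#' @param insert_sd_bp insert size standard deviation.
#' @param genome_size_bp genome size used for coverage reporting; defaults
#'   to the length of the sequence being cloned (set it to the full genome
#'   size, e.g. 632 Mb, when reporting a scale-up).
#' @param empty_clone_prob probability a clone carries no insert.
#' @param seed integer seed.
#' @return list of class `bac_library_params`.
#' @export
bac_library_params <- function(n_clones, insert_mean_bp = 130000,
                               insert_sd_bp = 13000, genome_size_bp = NULL,
                               empty_clone_prob = 0.018, seed = 1L) {
  stopifnot(n_clones >= 1, insert_mean_bp > 0, insert_sd_bp >= 0,
            empty_clone_prob >= 0, empty_clone_prob <= 1)
  structure(list(n_clones = as.integer(n_clones),
                 insert_mean_bp = insert_mean_bp, insert_sd_bp = insert_sd_bp,
                 genome_size_bp = genome_size_bp,
                 empty_clone_prob = empty_clone_prob, seed = as.integer(seed)),
            class = "bac_library_params")
}

#' In-silico HindIII digest
#'
#' Cuts the sequence at every occurrence of the HindIII site `AAGCTT`
#' between the first and second base (`A^AGCTT`) and returns the fragment
#' lengths in ascending order.  Fragment lengths always sum to the input
#' length.
#'
#' @param sequence DNA string over A/C/G/T.
#' @return sorted integer vector of fragment lengths.
#' @export
#' @examples
#' digest_hindiii("TTTAAGCTTGGG")  # 4 8
digest_hindiii <- function(sequence) {
  sequence <- check_dna(sequence, "sequence")
  hits <- Biostrings::matchPattern("AAGCTT", Biostrings::DNAString(sequence))
  cuts <- BiocGenerics::start(hits)  # cut after this position (A^AGCTT)
  sort(diff(c(0L, cuts, nchar(sequence))))
}

#' Simulate a BAC library with HindIII fingerprints
#'
#' Clone intervals are sampled uniformly along the sequence with
#' near-normal insert lengths; a clone is empty with probability
#' `empty_clone_prob`.  Each non-empty clone's fingerprint is the HindIII
#' digest of its insert; empty clones are flagged and have no bands.
#'
#' @param genome_sequence the DNA sequence the library is made from; must
#'   be longer than the mean insert.
#' @param params a [bac_library_params()].
#' @return list of class `bac_library`: `clones` (data frame `id`, `start`,
#'   `end`, `empty`), `fingerprints` (named list of sorted band vectors),
#'   `params`.
#' @export
simulate_bac_library <- function(genome_sequence, params) {
  stopifnot(inherits(params, "bac_library_params"))
  genome_sequence <- check_dna(genome_sequence, "genome_sequence")
  L <- nchar(genome_sequence)
  if (L <= params$insert_mean_bp) {
    stop("genome_sequence (", L, " bp) must be longer than the mean insert")
  }
  set.seed(params$seed)
  n <- params$n_clones
  len <- pmin(pmax(as.integer(round(stats::rnorm(n, params$insert_mean_bp,
                                                 params$insert_sd_bp))),
                   1000L), L - 1L)
  start <- vapply(len, function(l) sample.int(L - l + 1L, 1L), 0L)
  empty <- stats::runif(n) < params$empty_clone_prob
  ids <- sprintf("BAC%04d", seq_len(n))
  fps <- vector("list", n)
  names(fps) <- ids
  for (i in seq_len(n)) {
    fps[[i]] <- if (empty[i]) numeric(0) else
      digest_hindiii(substring(genome_sequence, start[i], start[i] + len[i] - 1L))
  }
  out <- list(
    clones = data.frame(id = ids, start = start, end = start + len - 1L,
                        empty = empty, stringsAsFactors = FALSE),
    fingerprints = fps,
    params = params
  )
  class(out) <- "bac_library"
  out
}

#' @export
print.bac_library <- function(x, ...) {
  cat(sprintf("bac_library: %d clones (%d empty), mean insert %.0f bp\n",
              nrow(x$clones), sum(x$clones$empty),
              mean(x$clones$end - x$clones$start + 1)))
  invisible(x)
}

#' Simulate a probe hybridisation screen of a clone library
#'
#' A non-empty clone is positive for a probe when its interval overlaps a
#' retained homologous locus of that probe's gene by at least
#' `min_overlap_bp`.  A probe whose gene is retained nowhere scores zero
#' positives over zero loci (not an error).
#'
#' @param clones data frame with `id`, `start`, `end` and optionally
#'   `empty` (a [simulate_bac_library()] `clones` element).
#' @param probe_loci data frame of retained homologous loci: columns
#'   `probe`, `start`, `end`.
#' @param min_overlap_bp minimum overlap for detection (default 1000).
#' @param probes probe ids to report (default: those in `probe_loci`).
#' @return list of class `probe_screen`: `table` (data frame `probe`,
#'   `n_positive`, `n_loci`, `mean_redundancy`) and `positives` (named list
#'   of positive clone ids per probe).
#' @export
simulate_probe_screen <- function(clones, probe_loci, min_overlap_bp = 1000,
                                  probes = unique(probe_loci$probe)) {
  stopifnot(all(c("id", "start", "end") %in% names(clones)),
            all(c("probe", "start", "end") %in% names(probe_loci)),
            min_overlap_bp >= 1)
  usable <- if ("empty" %in% names(clones)) !clones$empty else
    rep(TRUE, nrow(clones))
  positives <- stats::setNames(vector("list", length(probes)), probes)
  tab <- data.frame(probe = probes, n_positive = 0L, n_loci = 0L,
                    mean_redundancy = NA_real_, stringsAsFactors = FALSE)
  for (pi in seq_along(probes)) {
    loci <- probe_loci[probe_loci$probe == probes[pi], , drop = FALSE]
    tab$n_loci[pi] <- nrow(loci)
    if (nrow(loci) == 0L) {
      positives[[pi]] <- character(0)
      next
    }
    pos <- logical(nrow(clones))
    for (li in seq_len(nrow(loci))) {
      ov <- pmin(clones$end, loci$end[li]) - pmax(clones$start, loci$start[li]) + 1
      pos <- pos | (ov >= min_overlap_bp)
    }
    pos <- pos & usable
    positives[[pi]] <- clones$id[pos]
    tab$n_positive[pi] <- sum(pos)
    tab$mean_redundancy[pi] <- mean_redundancy(sum(pos), nrow(loci))
  }
  tab$n_loci[tab$n_positive == 0L & tab$n_loci == 0L] <- 0L
  out <- list(table = tab, positives = positives)
  class(out) <- "probe_screen"
  out
}

#' @export
print.probe_screen <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Concatenate genome copies into a single cloneable sequence
#'
#' Joins the given copies with random spacer sequence (emulating the rest
#' of the genome between the studied regions) and returns the concatenated
#' sequence together with per-copy offsets and the genomic intervals of
#' every annotated gene, keyed by ancestral id — the loci a gene-specific
#' probe can detect.
#'
#' @param copies named list of `genome_copy` objects (e.g. the three B
#'   sub-genome copies).
#' @param spacer_bp spacer length between regions (default 50 kb).
#' @param total_bp optional minimum total length; remaining filler is
#'   appended (to emulate a larger genome for library coverage).
#' @param seed seed for the random spacer sequence.
#' @return list with `sequence`, `offsets` (named, 0-based offset per
#'   copy), and `loci` (data frame `probe` (ancestral gene id), `copy`,
#'   `start`, `end`).
#' @export
concat_genome <- function(copies, spacer_bp = 50000, total_bp = NULL, seed = 1L) {
  stopifnot(length(copies) >= 1, all(vapply(copies, inherits, TRUE, "genome_copy")))
  set.seed(as.integer(seed))
  parts <- character(0)
  offsets <- stats::setNames(numeric(length(copies)), names(copies))
  loci <- list()
  pos <- 0L
  for (nm in names(copies)) {
    cpy <- copies[[nm]]
    offsets[[nm]] <- pos
    g <- cpy$genes[!is.na(cpy$genes$ancestral_id), , drop = FALSE]
    if (nrow(g)) {
      loci[[length(loci) + 1L]] <- data.frame(
        probe = g$ancestral_id, copy = nm,
        start = g$start + pos, end = g$end + pos, stringsAsFactors = FALSE)
    }
    parts <- c(parts, cpy$sequence)
    pos <- pos + nchar(cpy$sequence)
    parts <- c(parts, random_dna(spacer_bp))
    pos <- pos + spacer_bp
  }
  if (!is.null(total_bp) && pos < total_bp) {
    parts <- c(parts, random_dna(total_bp - pos))
    pos <- total_bp
  }
  list(sequence = paste(parts, collapse = ""),
       offsets = offsets,
       loci = if (length(loci)) do.call(rbind, loci) else
         data.frame(probe = character(0), copy = character(0),
                    start = integer(0), end = integer(0)))
}
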