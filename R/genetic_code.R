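# Codon machinery shared by the simulator and the NG86 estimator.
# All tables are built once per session and cached in .codon_env.

.codon_env <- new.env(parent = emptyenv())

#' All 64 codons in a fixed order
#' @return character vector of codons (TTT, TTC, ... in base order T,C,A,G? No:
#'   lexicographic over A,C,G,T), standard genetic code.
#' @keywords internal
codon_universe <- function() {
  if (is.null(.codon_env$codons)) {
    b <- c("A", "C", "G", "T")
    .codon_env$codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
    .codon_env$aa <- unname(Biostrings::GENETIC_CODE[.codon_env$codons])
  }
  .codon_env$codons
}

codon_aa <- function() {
  codon_universe()
  .codon_env$aa
}

#' Translate a codon string to an amino acid (standard code, `*` = stop)
#' @keywords internal
translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# 64 x 9 matrix of single-nucleotide neighbour codon indices, and a parallel
# character matrix classifying each mutation as "syn", "nonsyn" or "stop"
# (relative to the source codon; stop-source rows are NA).
codon_neighbors <- function() {
  if (!is.null(.codon_env$nbr)) {
    return(list(idx = .codon_env$nbr, type = .codon_env$nbr_type))
  }
  codons <- codon_universe()
  aa <- codon_aa()
  bases <- c("A", "C", "G", "T")
  nbr <- matrix(NA_integer_, 64L, 9L)
  typ <- matrix(NA_character_, 64L, 9L)
  for (i in seq_len(64L)) {
    cd <- strsplit(codons[i], "")[[1L]]
    col <- 0L
    for (pos in 1:3) {
      for (alt in setdiff(bases, cd[pos])) {
        col <- col + 1L
        cd2 <- cd
        cd2[pos] <- alt
        j <- match(paste(cd2, collapse = ""), codons)
        nbr[i, col] <- j
        if (aa[i] == "*") next
        typ[i, col] <- if (aa[j] == "*") "stop" else if (aa[j] == aa[i]) "syn" else "nonsyn"
      }
    }
  }
  .codon_env$nbr <- nbr
  .codon_env$nbr_type <- typ
  list(idx = nbr, type = typ)
}

#' Synonymous site fractions of a codon (NG86)
#'
#' For each codon position, the fraction of the three single-nucleotide
#' changes that are synonymous; changes creating a stop codon are excluded
#' from the denominator, following Nei & Gojobori (1986).  The sum of the
#' three fractions is the codon's contribution to the synonymous site count
#' S; its nonsynonymous contribution is `3 - sum`.
#'
#' @param codon a single sense codon, e.g. `"TTT"`.
#' @return numeric vector of length 3 (per-position synonymous fractions).
#' @export
#' @examples
#' sum(count_sites_ng86("TTT"))  # 1/3: only TTT->TTC is synonymous
#' sum(count_sites_ng86("ATG"))  # 0: Met has no synonymous neighbour
#' sum(count_sites_ng86("GGG"))  # 1: third position fully synonymous
count_sites_ng86 <- function(codon) {
  stopifnot(is.character(codon), length(codon) == 1L, nchar(codon) == 3L)
  codon <- toupper(codon)
  i <- match(codon, codon_universe())
  if (is.na(i)) stop("not a codon: ", codon)
  if (codon_aa()[i] == "*") stop("stop codon has no NG86 site counts: ", codon)
  typ <- codon_neighbors()$type[i, ]
  out <- numeric(3L)
  for (pos in 1:3) {
    t3 <- typ[(pos - 1L) * 3L + 1:3]
    denom <- sum(t3 != "stop")
    out[pos] <- if (denom == 0L) 0 else sum(t3 == "syn") / denom
  }
  out
}

# Per-codon total synonymous sites for all 64 codons (NA for stops), cached.
codon_syn_sites <- function() {
  if (is.null(.codon_env$ssites)) {
    codons <- codon_universe()
    aa <- codon_aa()
    s <- rep(NA_real_, 64L)
    for (i in seq_len(64L)) {
      if (aa[i] != "*") s[i] <- sum(count_sites_ng86(codons[i]))
    }
    .codon_env$ssites <- s
  }
  .codon_env$ssites
}

# Pathway-averaged (Sd, Nd) contributions for every ordered sense-codon pair,
# cached as two 64 x 64 matrices.  Multi-nucleotide differences are resolved
# by averaging over all orderings of the differing positions; orderings that
# pass through a stop codon are excluded (if every ordering does, all are
# kept — the NG86 fallback).
codon_pair_diffs <- function() {
  if (!is.null(.codon_env$sd)) {
    return(list(sd = .codon_env$sd, nd = .codon_env$nd))
  }
  codons <- codon_universe()
  aa <- codon_aa()
  sd <- matrix(NA_real_, 64L, 64L)
  nd <- matrix(NA_real_, 64L, 64L)
  perms <- list(
    `1` = list(1L),
    `2` = list(c(1L, 2L), c(2L, 1L)),
    `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  for (i in seq_len(64L)) {
    if (aa[i] == "*") next
    ci <- strsplit(codons[i], "")[[1L]]
    for (j in seq_len(64L)) {
      if (aa[j] == "*") next
      cj <- strsplit(codons[j], "")[[1L]]
      dpos <- which(ci != cj)
      ndiff <- length(dpos)
      if (ndiff == 0L) {
        sd[i, j] <- 0
        nd[i, j] <- 0
        next
      }
      paths <- perms[[as.character(ndiff)]]
      res <- matrix(NA_real_, length(paths), 2L)
      ok <- logical(length(paths))
      for (p in seq_along(paths)) {
        cur <- ci
        s_ct <- 0
        n_ct <- 0
        valid <- TRUE
        for (pos in dpos[paths[[p]]]) {
          nxt <- cur
          nxt[pos] <- cj[pos]
          a1 <- translate_codon(paste(cur, collapse = ""))
          a2 <- translate_codon(paste(nxt, collapse = ""))
          if (a2 == "*") valid <- FALSE  # path passes through a stop
          if (identical(a1, a2)) s_ct <- s_ct + 1 else n_ct <- n_ct + 1
          cur <- nxt
        }
        res[p, ] <- c(s_ct, n_ct)
        ok[p] <- valid
      }
      use <- if (any(ok)) ok else rep(TRUE, length(paths))
      sd[i, j] <- mean(res[use, 1L])
      nd[i, j] <- mean(res[use, 2L])
    }
  }
  .codon_env$sd <- sd
  .codon_env$nd <- nd
  list(sd = sd, nd = nd)
}

# Split a CDS string into codon indices into codon_universe().
cds_to_codons <- function(cds) {
  cds <- check_dna(cds, "CDS")
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  n <- nchar(cds) %/% 3L
  starts <- (seq_len(n) - 1L) * 3L + 1L
  match(substring(cds, starts, starts + 2L), codon_universe())
}

codons_to_cds <- function(idx) {
  paste(codon_universe()[idx], collapse = "")
}
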