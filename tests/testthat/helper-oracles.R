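# Independent brute-force oracles used to validate the package's
# algorithms.  Each is written as directly as possible (exhaustive
# enumeration or full dynamic programming) and shares no code with the
# implementation it checks.

# Affine-gap local alignment (Smith-Waterman) score by full DP.
# A gap of length L costs open + L * extend (positive penalties).
oracle_sw_score <- function(a, b, match = 1, mismatch = -1,
                            open = 2, extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)      # match/mismatch state
  X <- matrix(-Inf, n + 1, m + 1)   # gap in b (consume a)
  Y <- matrix(-Inf, n + 1, m + 1)   # gap in a (consume b)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Best local score over both strands (mirrors align_local's contract).
oracle_sw_score_2str <- function(q, t, ...) {
  max(oracle_sw_score(q, t, ...), oracle_sw_score(hexafrac::revcomp(q), t, ...))
}

# Global affine protein alignment score (Needleman-Wunsch with end-gap
# penalties), for checking the aligner behind codon_align.
oracle_nw_protein_score <- function(pa, pb, open = 10, extend = 1) {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  B <- data_env$BLOSUM62
  av <- strsplit(pa, "")[[1]]
  bv <- strsplit(pb, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - extend * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - extend * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- B[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# NG86 pathway counts for one codon pair by explicit depth-first
# enumeration of mutation orderings; pathways through stop codons are
# excluded unless all are blocked.
oracle_ng86_pair <- function(ca, cb) {
  code <- Biostrings::GENETIC_CODE
  va <- strsplit(ca, "")[[1]]
  vb <- strsplit(cb, "")[[1]]
  dpos <- which(va != vb)
  if (!length(dpos)) return(c(sd = 0, nd = 0))
  paths <- list()
  walk <- function(cur, remaining, s, n, blocked) {
    if (!length(remaining)) {
      paths[[length(paths) + 1]] <<- c(s, n, blocked)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- vb[p]
      aa1 <- code[[paste(cur, collapse = "")]]
      aa2 <- code[[paste(nxt, collapse = "")]]
      walk(nxt, setdiff(remaining, p),
           s + as.integer(aa1 == aa2 && aa2 != "*"),
           n + as.integer(aa1 != aa2 || aa2 == "*"),
           blocked || aa2 == "*")
    }
  }
  walk(va, dpos, 0L, 0L, FALSE)
  m <- do.call(rbind, paths)
  ok <- m[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(sd = mean(m[ok, 1]), nd = mean(m[ok, 2]))
}

# NG86 synonymous-site fraction of a codon by enumerating all 9 mutations.
oracle_syn_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  v <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0; nonstop <- 0
    for (alt in setdiff(c("A", "C", "G", "T"), v[pos])) {
      w <- v; w[pos] <- alt
      aa <- code[[paste(w, collapse = "")]]
      if (aa == "*") next
      nonstop <- nonstop + 1
      if (aa == code[[codon]]) syn <- syn + 1
    }
    if (nonstop > 0) total <- total + syn / nonstop
  }
  total
}

# Minimal Dollo loss placements by enumerating all 2^5 branch subsets.
# A tip is present iff no branch on its root path carries a loss.
oracle_dollo <- function(present) {
  branches <- c("stem_ABC", "stem_AC", "term_A", "term_B", "term_C")
  paths <- list(A = c(1, 2, 3), B = c(1, 4), C = c(1, 2, 5))
  feasible <- list()
  for (mask in 0:31) {
    S <- which(bitwAnd(mask, 2^(0:4)) > 0)
    ok <- TRUE
    for (tip in c("A", "B", "C")) {
      killed <- length(intersect(S, paths[[tip]])) > 0
      if (killed == present[[tip]]) { ok <- FALSE; break }
    }
    if (ok) feasible[[length(feasible) + 1]] <- branches[S]
  }
  sizes <- lengths(feasible)
  feasible[sizes == min(sizes)]
}

# All maximal exact matches by per-diagonal vectorised scanning (both
# strands); O(n*m) overall.
oracle_mems <- function(a, b, min_len) {
  one <- function(a, b) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    n <- length(av); m <- length(bv)
    rows <- list()
    for (d in (-(m - 1)):(n - 1)) {
      ia <- max(1, 1 + d):min(n, m + d)
      ib <- ia - d
      eq <- av[ia] == bv[ib]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values & r$lengths >= min_len)) {
        rows[[length(rows) + 1]] <- data.frame(
          a_start = ia[starts[k]], b_start = ib[starts[k]],
          length = r$lengths[k])
      }
    }
    if (!length(rows)) {
      return(data.frame(a_start = integer(0), b_start = integer(0),
                        length = integer(0)))
    }
    do.call(rbind, rows)
  }
  plus <- one(a, b)
  if (nrow(plus)) plus$strand <- "+" else plus$strand <- character(0)
  brc <- hexafrac::revcomp(b)
  minus <- one(a, brc)
  if (nrow(minus)) {
    minus$b_start <- nchar(b) - (minus$b_start + minus$length - 1) + 1
    minus$strand <- "-"
  } else {
    minus$strand <- character(0)
  }
  out <- rbind(plus, minus)
  out[order(out$a_start, out$b_start), , drop = FALSE]
}

# Maximum-weight monotone (strictly increasing ref, strictly monotone
# target) subsequence weight by enumerating all subsets; n <= 15.
oracle_chain_weight <- function(ref_pos, t_start, score) {
  n <- length(ref_pos)
  best <- 0
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    idx <- idx[order(ref_pos[idx])]
    if (any(duplicated(ref_pos[idx]))) next
    ts <- t_start[idx]
    if (length(idx) > 1 && !(all(diff(ts) > 0) || all(diff(ts) < 0))) next
    best <- max(best, sum(score[idx]))
  }
  best
}

# Binomial tail of the Sulston formula via explicit log binomial
# coefficients.
oracle_sulston_tail <- function(m, nL, p) {
  if (m == 0) return(1)
  j <- m:nL
  sum(exp(lchoose(nL, j) + j * log(p) + (nL - j) * log1p(-p)))
}

# Random sense-codon CDS of n codons starting ATG and ending with a stop.
random_cds <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  stopc <- names(code)[code == "*"]
  paste(c("ATG", sample(sense, n_codons - 2, replace = TRUE),
          sample(stopc, 1)), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
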