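#' Round half away from zero
#'
#' Deterministic decimal rounding in which a residual of exactly 5 in the
#' first dropped digit rounds up (`8.65 -> 8.7` at 1 dp).  Used for all
#' percentage and density reporting; contrast with [round_half_down()] and
#' with base [round()], which rounds half to even.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits number of decimal places to keep.
#' @return `x` rounded to `digits` decimal places.
#' @export
#' @examples
#' round_half_up(53.3505, 2)  # 53.35
#' round_half_up(8.65, 1)     # 8.7
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Round half toward zero
#'
#' Companion to [round_half_up()]: a residual of exactly 5 in the first
#' dropped digit rounds down (`8.75 -> 8.7` at 1 dp).  Used for the 1-dp
#' clone-count ratios (redundancy, coverage, empty rate), whose published
#' values follow this convention.
#'
#' @inheritParams round_half_up
#' @return `x` rounded to `digits` decimal places.
#' @export
round_half_down <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  f <- 10^digits
  sign(x) * ceiling(abs(x) * f - 0.5) / f
}

#' Derive a reproducible per-stage seed from a global seed
#'
#' Fans a single pipeline seed out to independent stage seeds by hashing the
#' stage name, so rerunning one stage never perturbs another.  The result is
#' always a valid 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((abs(seed) + h) %% .Machine$integer.max)
}

# Internal: uppercase DNA validation. Returns the uppercased string or stops.
check_dna <- function(x, what = "sequence") {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  if (nchar(x) == 0L) stop(what, " is empty")
  if (grepl("[^ACGT]", x)) {
    bad <- regmatches(x, regexpr("[^ACGT]", x))
    stop(what, " contains non-ACGT character '", bad, "'")
  }
  x
}

# Internal: random DNA string of length n under the current RNG state.
random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA string
#'
#' Character-in/character-out; short strings are handled in base R, long
#' ones through [Biostrings::reverseComplement()].
#'
#' @param x a single DNA string (A/C/G/T).
#' @return the reverse complement as a character string.
#' @export
revcomp <- function(x) {
  if (nchar(x) <= 20000L) {
    return(paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), NULL)[[1L]]),
                 collapse = ""))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Internal: mutate non-coding sequence under a per-site substitution
# probability; vectorised, no selection.
mutate_neutral <- function(seq, p_sub) {
  n <- nchar(seq)
  if (n == 0L || p_sub <= 0) return(seq)
  k <- stats::rbinom(1L, n, min(p_sub, 1))
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  for (i in pos) {
    chars[i] <- sample(setdiff(bases, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}
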