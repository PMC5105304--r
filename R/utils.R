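# Low-level sequence/string helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Longest homopolymer run of a given base
#'
#' @param x single DNA string.
#' @param base single character, e.g. "A".
#' @return integer, length of the longest run of `base` in `x` (0 if absent).
#' @keywords internal
longest_run <- function(x, base) {
  if (is.na(x) || nchar(x) == 0L) return(0L)
  r <- rle(strsplit(x, "", fixed = TRUE)[[1]] == base)
  runs <- r$lengths[r$values]
  if (length(runs) == 0L) 0L else max(runs)
}

# Longest run of A or of T (either base, not mixed), as used by the
# junction-read polyA/polyT filter.
longest_at_run <- function(x) {
  max(longest_run(x, "A"), longest_run(x, "T"))
}

# Random DNA with slight AT bias (human-like base composition).
random_dna <- function(n, at = 0.6) {
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Longest common prefix length of two strings.
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- utf8ToInt(substr(a, 1L, n))
  bv <- utf8ToInt(substr(b, 1L, n))
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

# Longest common suffix length of two strings.
common_suffix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- rev(utf8ToInt(a))[seq_len(n)]
  bv <- rev(utf8ToInt(b))[seq_len(n)]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

# Hamming distance between equal-length strings (vectorised over pairs).
hamming <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(integer(0))
  vapply(seq_along(a), function(i) {
    sum(charToRaw(a[[i]]) != charToRaw(b[[i]]))
  }, integer(1))
}

#' Derive a stage-specific RNG seed from a master seed
#'
#' Stage substreams keep reruns of individual stages reproducible without
#' sharing a stream with earlier stages. The result always fits a 32-bit
#' integer.
#'
#' @param seed master integer seed.
#' @param label stage label, e.g. "simulate".
#' @return integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483399 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
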