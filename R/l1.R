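# The synthetic L1 consensus element and its 3'UTR amplification anchor.
#
# The package ships a fixed, deterministic 6059 bp consensus standing in for
# the active human-specific L1Hs subfamily. 6059 bp equals the longest
# insertion the pipeline is expected to report, so a full-length implant is
# exactly one consensus copy. The vectorette amplification primer site
# ("anchor") sits in the element's 3'UTR, 340-359 bp upstream of the 3'
# terminus, which is what restricts the assay to 3' ends and lets severely
# 5'-truncated insertions be recovered.

L1_CONSENSUS_LENGTH <- 6059L
# distance of the anchor's first/last base from the element 3' end
L1_ANCHOR_FROM_3P <- c(far = 359L, near = 340L)
L1_FIXED_POLYA <- 20L   # polyA tail length given to fixed reference copies

.tipseqr_cache <- new.env(parent = emptyenv())

#' The package's L1 consensus element
#'
#' A fixed 6059 bp synthetic consensus with AT-biased composition. The
#' terminal base is forced to a non-A so that the polyA tail appended at
#' implant time remains exactly recoverable, and the first base to a non-T so
#' that minus-strand tails are equally unambiguous.
#'
#' @return list with `sequence` (character), `anchor_start`, `anchor_end`
#'   (1-based element coordinates of the amplification primer site),
#'   and `polyA_template_length`.
#' @export
l1_consensus <- function() {
  if (!is.null(.tipseqr_cache$l1)) return(.tipseqr_cache$l1)
  seq <- withr::with_seed(600959L, random_dna(L1_CONSENSUS_LENGTH, at = 0.6))
  # pin terminal bases for unambiguous tail/strand recovery
  substr(seq, 1L, 1L) <- "G"
  substr(seq, L1_CONSENSUS_LENGTH, L1_CONSENSUS_LENGTH) <- "C"
  anchor_start <- L1_CONSENSUS_LENGTH - L1_ANCHOR_FROM_3P[["far"]]
  anchor_end <- L1_CONSENSUS_LENGTH - L1_ANCHOR_FROM_3P[["near"]]
  obj <- list(
    sequence = seq,
    anchor_start = anchor_start,
    anchor_end = anchor_end,
    polyA_template_length = L1_FIXED_POLYA
  )
  stopifnot(anchor_start > floor(0.9 * L1_CONSENSUS_LENGTH))
  .tipseqr_cache$l1 <- obj
  obj
}

# The anchor primer subsequence itself (20 bp).
l1_anchor_seq <- function() {
  l1 <- l1_consensus()
  substr(l1$sequence, l1$anchor_start, l1$anchor_end)
}

#' 3' L1 probe with polyA tail
#'
#' The reference sequence used when classifying junction consensus sequences:
#' the element's 3' terminal portion followed by a polyA stretch, mirroring
#' the "3' LINE-1 sequence with polyA tail" comparison target.
#'
#' @param tail_bp how much of the element 3' end to include.
#' @param polyA_bp length of the appended polyA stretch.
#' @return character scalar.
#' @export
l1_three_prime_probe <- function(tail_bp = 1000L, polyA_bp = 30L) {
  l1 <- l1_consensus()
  paste0(
    substr(l1$sequence, L1_CONSENSUS_LENGTH - tail_bp + 1L, L1_CONSENSUS_LENGTH),
    strrep("A", polyA_bp)
  )
}

# Minimum 3' (non-inverted) element extent for an insertion to carry the
# amplification anchor and therefore be recoverable by the assay.
l1_min_amplifiable <- function() {
  L1_ANCHOR_FROM_3P[["far"]] + 1L
}

# default-consensus accessor usable where a parameter shadows the name
.l1_default_sequence <- function() l1_consensus()$sequence
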