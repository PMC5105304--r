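# Restriction enzymes used for the parallel vectorette digests. Only the
# recognition sequence matters to the simulator: an amplicon runs from the
# L1 3'UTR anchor through the polyA tail and downstream flank to the first
# recognition site. BstYI has a degenerate site (R = A/G, Y = C/T), matched
# through IUPAC-aware Biostrings search.

#' Default vectorette restriction enzyme panel
#'
#' @return data.frame with columns `name` and `site` (IUPAC recognition
#'   sequence).
#' @export
vectorette_enzymes <- function() {
  data.frame(
    name = c("AseI", "BspHI", "BstYI", "HindIII", "NcoI", "PstI"),
    site = c("ATTAAT", "TCATGA", "RGATCY", "AAGCTT", "CCATGG", "CTGCAG"),
    stringsAsFactors = FALSE
  )
}

# First recognition-site start at or after `from` (direction +1) or at or
# before `from` (direction -1) on `seq`; NA when none in the searched window.
first_site <- function(seq, site, from, direction, max_dist) {
  n <- nchar(seq)
  w <- nchar(site)
  if (direction > 0) {
    lo <- from
    hi <- min(n, from + max_dist + w)
  } else {
    lo <- max(1L, from - max_dist - w)
    hi <- from
  }
  if (hi - lo + 1L < w) return(NA_integer_)
  window <- Biostrings::DNAString(substr(seq, lo, hi))
  m <- Biostrings::matchPattern(site, window, fixed = FALSE)
  if (length(m) == 0L) return(NA_integer_)
  st <- BiocGenerics::start(m) + lo - 1L
  if (direction > 0) st[1L] else st[length(st)]
}
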