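# Internal short-read alignment: exact k-mer seeding (Biostrings matchPDict)
# followed by ungapped extension that counts mismatches. With s seeds spread
# across a read, any placement with at most s-1 mismatches is guaranteed to
# be seeded (pigeonhole); seeds are provisioned so that every placement
# within max_mismatches + 1 is found, which makes the unique/multi decision
# identical to an exhaustive scan. N in the reference never matches.

# seed offsets (1-based, within the oriented read) for one read length
seed_offsets <- function(len, k, max_mm) {
  n_seeds <- max(2L, max_mm + 2L)
  unique(round(seq(1L, len - k + 1L, length.out = n_seeds)))
}

#' Align reads to a reference by seed-and-extend
#'
#' Best ungapped placement per read over both strands. A read is `unique`
#' when exactly one placement attains the best mismatch count within the
#' allowance and beats the runner-up by at least `unique_margin`
#' mismatches, `multi` when several placements tie or come close, and
#' `unmapped` when no placement is within the allowance.
#'
#' @param reads data.frame(read_id, seq) or named character vector.
#' @param reference `tip_genome` or named character vector of chromosome
#'   sequences (typically the L1-masked reference).
#' @param k seed length.
#' @param max_mismatch_rate mismatch allowance per aligned base (default 3
#'   per 100 bp).
#' @param unique_margin minimum mismatch gap to the runner-up for a unique
#'   call.
#' @return data.frame(read_id, chrom, start, end, strand, mismatches,
#'   status) with one row per read; unmapped rows carry NA coordinates.
#' @export
align_reads <- function(reads, reference, k = 20L,
                        max_mismatch_rate = 0.03, unique_margin = 2L) {
  if (is.character(reads)) {
    reads <- data.frame(
      read_id = names(reads) %||% sprintf("read%06d", seq_along(reads)),
      seq = unname(reads), stringsAsFactors = FALSE
    )
  }
  chroms <- if (inherits(reference, "tip_genome")) {
    reference$chromosomes
  } else {
    reference
  }
  n <- nrow(reads)
  out <- data.frame(
    read_id = if (n) reads$read_id else character(0),
    chrom = rep(NA_character_, n), start = rep(NA_integer_, n),
    end = rep(NA_integer_, n), strand = rep(NA_character_, n),
    mismatches = rep(NA_integer_, n),
    status = rep("unmapped", n), stringsAsFactors = FALSE
  )
  if (n == 0L) return(out)

  lens <- nchar(reads$seq)
  max_mm <- as.integer(floor(lens * max_mismatch_rate))
  alignable <- which(lens >= k)
  if (length(alignable) == 0L) return(out)

  oriented <- list("+" = reads$seq, "-" = revcomp(reads$seq))

  # seed table over both orientations (offsets depend only on read length)
  ulen <- unique(lens[alignable])
  offs_by_len <- lapply(ulen, function(l) {
    seed_offsets(l, k, as.integer(floor(l * max_mismatch_rate)))
  })
  names(offs_by_len) <- as.character(ulen)
  offs_list <- offs_by_len[as.character(lens[alignable])]
  n_offs <- lengths(offs_list)
  one_read <- rep(alignable, n_offs)
  one_off <- unlist(offs_list, use.names = FALSE)
  seed_read <- rep(one_read, 2L)
  seed_off <- rep(one_off, 2L)
  seed_strand <- rep(c("+", "-"), each = length(one_read))
  seed_seq <- c(
    substring(oriented[["+"]][one_read], one_off, one_off + k - 1L),
    substring(oriented[["-"]][one_read], one_off, one_off + k - 1L)
  )
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed_seq))

  cand <- list()
  for (cn in names(chroms)) {
    subj <- Biostrings::DNAString(chroms[[cn]])
    m <- Biostrings::matchPDict(pd, subj)
    si <- Biostrings::startIndex(m)
    cnt <- lengths(si)
    hit_seed <- rep(seq_along(cnt), cnt)
    if (length(hit_seed) == 0L) next
    hit_start <- unlist(si, use.names = FALSE)
    ri <- seed_read[hit_seed]
    st <- hit_start - seed_off[hit_seed] + 1L
    keep <- st >= 1L & st + lens[ri] - 1L <= nchar(chroms[[cn]])
    if (!any(keep)) next
    cand[[length(cand) + 1L]] <- data.frame(
      read = ri[keep], strand = seed_strand[hit_seed][keep],
      chrom = cn, start = st[keep], stringsAsFactors = FALSE
    )
  }
  if (length(cand) == 0L) return(out)
  cand <- do.call(rbind, cand)
  cand <- cand[!duplicated(cand), , drop = FALSE]

  # extension: count mismatches of the oriented read against the reference
  cand$mm <- NA_integer_
  for (cn in unique(cand$chrom)) {
    sel <- cand$chrom == cn
    ref_sub <- substring(chroms[[cn]], cand$start[sel],
                         cand$start[sel] + lens[cand$read[sel]] - 1L)
    rd <- ifelse(cand$strand[sel] == "+",
                 oriented[["+"]][cand$read[sel]],
                 oriented[["-"]][cand$read[sel]])
    cand$mm[sel] <- hamming(rd, ref_sub)
  }

  valid <- cand[cand$mm <= max_mm[cand$read], , drop = FALSE]
  if (nrow(valid) == 0L) return(out)
  valid <- valid[order(valid$read, valid$mm, valid$chrom, valid$start,
                       valid$strand), , drop = FALSE]
  for (idx in split(seq_len(nrow(valid)), valid$read)) {
    v <- valid[idx, , drop = FALSE]
    i <- v$read[1L]
    best <- v$mm[1L]
    n_best <- sum(v$mm == best)
    runner <- if (nrow(v) > 1L) v$mm[2L] else Inf
    status <- if (n_best > 1L || (runner - best) < unique_margin) {
      "multi"
    } else {
      "unique"
    }
    out$chrom[i] <- v$chrom[1L]
    out$start[i] <- v$start[1L]
    out$end[i] <- v$start[1L] + lens[i] - 1L
    out$strand[i] <- v$strand[1L]
    out$mismatches[i] <- best
    out$status[i] <- status
  }
  out
}

#' Best local alignment of a sequence against the L1 consensus
#'
#' Smith-Waterman local alignment (via Biostrings) of the query against the
#' element in both orientations. Identity is defined as matching bases over
#' the full query length, so a short chance match in a long random query
#' does not count as a hit.
#'
#' @param sequence query DNA string.
#' @param l1_consensus element (or 3' probe) sequence; defaults to the
#'   package consensus.
#' @param min_identity minimum query-coverage identity for a hit.
#' @return NULL when no hit reaches `min_identity`, else list(element_start,
#'   element_end, query_start, query_end, orientation, identity, score).
#' @export
align_to_l1 <- function(sequence, l1_consensus = NULL,
                        min_identity = 0.9) {
  stopifnot(nchar(sequence) > 0)
  if (is.null(l1_consensus)) l1_consensus <- .l1_default_sequence()
  subj <- Biostrings::DNAString(l1_consensus)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  best <- NULL
  for (ori in c("forward", "reverse")) {
    q <- if (ori == "forward") sequence else revcomp(sequence)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(q), subj, type = "local",
      substitutionMatrix = mat, gapOpening = 4, gapExtension = 1
    )
    identity <- Biostrings::nmatch(aln) / nchar(sequence)
    if (identity < min_identity) next
    qs <- BiocGenerics::start(Biostrings::pattern(aln))
    qe <- BiocGenerics::end(Biostrings::pattern(aln))
    if (ori == "reverse") {
      tmp <- qs
      qs <- nchar(sequence) - qe + 1L
      qe <- nchar(sequence) - tmp + 1L
    }
    hit <- list(
      element_start = BiocGenerics::start(Biostrings::subject(aln)),
      element_end = BiocGenerics::end(Biostrings::subject(aln)),
      query_start = qs, query_end = qe,
      orientation = ori, identity = identity,
      score = Biostrings::score(aln)
    )
    if (is.null(best) || hit$score > best$score) best <- hit
  }
  best
}
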