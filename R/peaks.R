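# Approach 1: coverage peaks ranked by maximum per-base depth, split-end
# junction-read recovery with a polyA/polyT run filter, anchored
# majority-vote consensus building, and dual classification of the
# consensus against the genome and the L1 3' + polyA probe.

#' Call coverage peaks from read alignments
#'
#' Maximal runs of covered positions (uniquely aligned reads), merging gaps
#' up to `max_gap`, ranked by maximum per-base depth with (chrom, start) as
#' the deterministic tie-break.
#'
#' @param alignments data.frame from [align_reads()].
#' @param min_reads minimum reads per peak.
#' @param max_gap coverage gaps up to this many bp are bridged.
#' @return data.frame(peak_id, chrom, start, end, read_count, max_coverage,
#'   rank), sorted by rank.
#' @export
call_peaks <- function(alignments, min_reads = 3L, max_gap = 100L) {
  empty <- data.frame(
    peak_id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), read_count = integer(0), max_coverage = integer(0),
    rank = integer(0), stringsAsFactors = FALSE
  )
  aln <- alignments[alignments$status == "unique", , drop = FALSE]
  if (nrow(aln) == 0L) return(empty)
  rows <- list()
  for (cn in sort(unique(aln$chrom))) {
    a <- aln[aln$chrom == cn, , drop = FALSE]
    ir <- IRanges::IRanges(start = a$start, end = a$end)
    cov <- IRanges::coverage(ir)
    covered <- IRanges::ranges(IRanges::slice(cov, lower = 1L))
    merged <- IRanges::reduce(covered, min.gapwidth = max_gap + 1L)
    if (length(merged) == 0L) next
    rc <- IRanges::countOverlaps(merged, ir)
    mx <- IRanges::viewMaxs(IRanges::Views(cov, merged))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = cn, start = BiocGenerics::start(merged),
      end = BiocGenerics::end(merged),
      read_count = rc, max_coverage = as.integer(mx),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) return(empty)
  pk <- do.call(rbind, rows)
  pk <- pk[pk$read_count >= min_reads, , drop = FALSE]
  if (nrow(pk) == 0L) return(empty)
  pk <- pk[order(-pk$max_coverage, pk$chrom, pk$start), , drop = FALSE]
  pk$rank <- seq_len(nrow(pk))
  pk$peak_id <- sprintf("%s:%d-%d", pk$chrom, pk$start, pk$end)
  rownames(pk) <- NULL
  pk[, c("peak_id", "chrom", "start", "end", "read_count", "max_coverage",
         "rank")]
}

# polyA tail purity of one overhang: max base fraction (A or T) over the
# longest mononucleotide-dominated window around the overhang's longest
# A-or-T run, padded to `window` bp. Declared interpretation of "polyA tail
# purity"; isolated here so it can be swapped.
polyA_tail_purity <- function(overhang, window = 20L) {
  if (is.na(overhang) || nchar(overhang) == 0L) return(0)
  ch <- strsplit(overhang, "", fixed = TRUE)[[1]]
  best <- 0
  for (base in c("A", "T")) {
    r <- rle(ch == base)
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    top <- runs[which.max(r$lengths[runs])]
    mid <- (starts[top] + ends[top]) %/% 2L
    half <- window %/% 2L
    lo <- max(1L, mid - half + 1L)
    hi <- min(length(ch), lo + window - 1L)
    best <- max(best, mean(ch[lo:hi] == base))
  }
  best
}

#' Extract junction reads for a set of peaks
#'
#' For each unmappable read, both `end_len`-bp ends are aligned separately;
#' reads where exactly one end aligns uniquely are junction candidates. The
#' unaligned remainder (overhang) must contain a run of at least
#' `min_polyAT` consecutive A or T. Each junction read is assigned to the
#' nearest peak within `window` bp and per-peak lists are truncated to
#' `cap` reads in deterministic (anchor coordinate, read id) order.
#'
#' @param unmapped_reads data.frame(read_id, seq) of unmapped reads.
#' @param masked_reference reference used for the end alignments.
#' @param peaks peak table from [call_peaks()].
#' @param end_len bp taken from each read end.
#' @param min_polyAT minimum A-or-T run length in the overhang.
#' @param cap maximum junction reads retained per peak.
#' @param window maximum distance from a peak for assignment.
#' @return data.frame with one row per retained junction read: peak
#'   assignment, anchor alignment, overhang in read orientation (`overhang`)
#'   and genome-plus orientation (`gseq`), the side of the anchor the
#'   overhang occupies (`side`), and the polyA/polyT run length. Reads
#'   shorter than `2 * end_len` are skipped and counted in the
#'   `skipped_short` attribute.
#' @export
extract_junction_reads <- function(unmapped_reads, masked_reference, peaks,
                                   end_len = 35L, min_polyAT = 6L,
                                   cap = 200L, window = 500L) {
  empty <- data.frame(
    peak_id = character(0), read_id = character(0),
    anchored_end = character(0), chrom = character(0),
    anchor_start = integer(0), anchor_end = integer(0),
    anchor_strand = character(0), anchor_mismatches = integer(0),
    side = character(0), overhang = character(0), gseq = character(0),
    polyAT_run = integer(0), stringsAsFactors = FALSE
  )
  attr(empty, "skipped_short") <- 0L
  if (nrow(unmapped_reads) == 0L || nrow(peaks) == 0L) return(empty)

  lens <- nchar(unmapped_reads$seq)
  short <- lens < 2L * end_len
  n_short <- sum(short)
  if (n_short > 0L) {
    message("extract_junction_reads: skipping ", n_short,
            " read(s) shorter than ", 2L * end_len, " bp")
  }
  rd <- unmapped_reads[!short, , drop = FALSE]
  lens <- lens[!short]
  if (nrow(rd) == 0L) {
    attr(empty, "skipped_short") <- n_short
    return(empty)
  }

  ends <- data.frame(
    read_id = c(paste0(rd$read_id, "|5p"), paste0(rd$read_id, "|3p")),
    seq = c(substr(rd$seq, 1L, end_len),
            substring(rd$seq, lens - end_len + 1L, lens)),
    stringsAsFactors = FALSE
  )
  ea <- align_reads(ends, masked_reference)
  a5 <- ea[seq_len(nrow(rd)), ]
  a3 <- ea[nrow(rd) + seq_len(nrow(rd)), ]

  u5 <- a5$status == "unique"
  u3 <- a3$status == "unique"
  keep <- xor(u5, u3)
  if (!any(keep)) {
    attr(empty, "skipped_short") <- n_short
    return(empty)
  }

  idx <- which(keep)
  anchored_end <- ifelse(u5[idx], "five_prime", "three_prime")
  anchor <- a5[idx, ]
  anchor[!u5[idx], ] <- a3[idx[!u5[idx]], ]
  overhang <- ifelse(
    u5[idx],
    substring(rd$seq[idx], end_len + 1L, lens[idx]),
    substr(rd$seq[idx], 1L, lens[idx] - end_len)
  )
  # orient the overhang to the genome plus strand and record which side of
  # the anchored segment it occupies
  plus <- anchor$strand == "+"
  five <- u5[idx]
  side <- ifelse(five == plus, "right", "left")
  # five_prime anchor on +: overhang follows in genome orientation (right).
  # five_prime on -: genome-plus overhang is the revcomp, to the left.
  # three_prime on +: overhang precedes the anchor (left), as read.
  # three_prime on -: revcomp, to the right.
  gseq <- ifelse(plus, overhang, revcomp(overhang))

  jr <- data.frame(
    peak_id = NA_character_, read_id = rd$read_id[idx],
    anchored_end = anchored_end, chrom = anchor$chrom,
    anchor_start = anchor$start, anchor_end = anchor$end,
    anchor_strand = anchor$strand, anchor_mismatches = anchor$mismatches,
    side = side, overhang = overhang, gseq = gseq,
    polyAT_run = vapply(overhang, longest_at_run, integer(1),
                        USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  jr <- jr[jr$polyAT_run >= min_polyAT, , drop = FALSE]
  if (nrow(jr) == 0L) {
    attr(empty, "skipped_short") <- n_short
    return(empty)
  }

  # assign to the nearest peak within the window
  for (cn in unique(jr$chrom)) {
    ji <- which(jr$chrom == cn)
    pk <- peaks[peaks$chrom == cn, , drop = FALSE]
    if (nrow(pk) == 0L) next
    for (j in ji) {
      gap <- pmax(0L, pmax(pk$start - jr$anchor_end[j],
                           jr$anchor_start[j] - pk$end))
      best <- which.min(gap)
      if (gap[best] <= window) jr$peak_id[j] <- pk$peak_id[best]
    }
  }
  jr <- jr[!is.na(jr$peak_id), , drop = FALSE]
  if (nrow(jr) == 0L) {
    attr(empty, "skipped_short") <- n_short
    return(empty)
  }

  # deterministic per-peak cap
  jr <- jr[order(jr$peak_id, jr$anchor_start, jr$read_id), , drop = FALSE]
  kept <- unlist(lapply(split(seq_len(nrow(jr)), jr$peak_id), function(ix) {
    ix[seq_len(min(length(ix), cap))]
  }), use.names = FALSE)
  jr <- jr[sort(kept), , drop = FALSE]
  rownames(jr) <- NULL
  attr(jr, "skipped_short") <- n_short
  jr
}

#' Build an anchored consensus from junction reads
#'
#' Overhangs are placed at genomic coordinates implied by their anchor
#' alignments (a center-star alignment degenerates to coordinate anchoring
#' because every overhang abuts its own anchor), then majority-voted per
#' column with ties broken A < C < G < T. The consensus is the longest
#' contiguous column run supported by at least two reads (one read when only
#' one exists).
#'
#' @param junction_reads rows of one peak from [extract_junction_reads()].
#' @return list(sequence, start, end, side, n_reads): `start`/`end` are the
#'   genomic coordinates the consensus columns occupy (positions left of the
#'   junction belong to the inserted element and exist only on the sample
#'   allele).
#' @export
build_consensus <- function(junction_reads) {
  if (is.null(junction_reads) || nrow(junction_reads) == 0L) {
    stop("build_consensus: no junction reads")
  }
  side_tab <- table(junction_reads$side)
  side <- names(side_tab)[which.max(side_tab)]  # ties: first name (left)
  jr <- junction_reads[junction_reads$side == side, , drop = FALSE]
  lens <- nchar(jr$gseq)
  coords <- vector("list", nrow(jr))
  for (i in seq_len(nrow(jr))) {
    coords[[i]] <- if (side == "left") {
      seq(jr$anchor_start[i] - lens[i], jr$anchor_start[i] - 1L)
    } else {
      seq(jr$anchor_end[i] + 1L, jr$anchor_end[i] + lens[i])
    }
  }
  pos <- unlist(coords, use.names = FALSE)
  base <- unlist(strsplit(jr$gseq, "", fixed = TRUE), use.names = FALSE)
  tab <- table(pos, factor(base, levels = DNA_BASES))
  support <- rowSums(tab)
  # which.max on the table row respects the A<C<G<T tie order
  winner <- DNA_BASES[apply(tab, 1L, which.max)]
  coord <- as.integer(rownames(tab))
  min_support <- if (nrow(jr) > 1L) 2L else 1L
  ok <- support >= min_support
  if (!any(ok)) stop("build_consensus: no column reaches support")
  # longest contiguous run of supported coordinates
  okc <- coord[ok]
  breaks <- c(0L, which(diff(okc) != 1L), length(okc))
  run_lens <- diff(breaks)
  top <- which.max(run_lens)
  run <- okc[(breaks[top] + 1L):breaks[top + 1L]]
  seqc <- paste(winner[ok][(breaks[top] + 1L):breaks[top + 1L]],
                collapse = "")
  list(sequence = seqc, start = run[1L], end = run[length(run)],
       side = side, n_reads = nrow(jr))
}

#' Classify a junction consensus against genome and L1 probe
#'
#' A consensus is `reference_only` when it matches the reference end-to-end
#' at the peak locus; `insertion_supported` when it splits into a uniquely
#' genome-matching part consistent with the locus plus a part matching the
#' L1 3' end / polyA probe (either orientation); `ambiguous` otherwise.
#'
#' @param consensus consensus string (or result of [build_consensus()]).
#' @param masked_reference reference genome (`tip_genome` or named vector).
#' @param l1_3prime_polyA probe from [l1_three_prime_probe()].
#' @param min_identity minimum query-coverage identity.
#' @param peak optional one-row peak table restricting the genome
#'   comparison to the locus neighborhood.
#' @return list(verdict, genome_identity, genome_range, l1_hit).
#' @export
classify_consensus <- function(consensus, masked_reference,
                               l1_3prime_polyA = l1_three_prime_probe(),
                               min_identity = 0.9, peak = NULL) {
  if (is.list(consensus)) consensus <- consensus$sequence
  stopifnot(nchar(consensus) > 0)
  chroms <- if (inherits(masked_reference, "tip_genome")) {
    masked_reference$chromosomes
  } else {
    masked_reference
  }
  pad <- nchar(consensus) + 3000L
  windows <- if (!is.null(peak)) {
    cn <- peak$chrom[1L]
    lo <- max(1L, peak$start[1L] - pad)
    hi <- min(nchar(chroms[[cn]]), peak$end[1L] + pad)
    stats::setNames(list(substr(chroms[[cn]], lo, hi)), cn)
  } else {
    as.list(chroms)
  }

  len <- nchar(consensus)
  # longest consensus suffix (and prefix) present in the locus window at
  # <=2% mismatches: a terminal genome-matching block ends exactly at the
  # junction, so this split is base-precise even next to the polyA tail
  occurs <- function(part) {
    # tolerate at least one mismatch: a single consensus voting error at a
    # terminal column must not hide the whole genome-matching block
    mism <- max(1L, as.integer(floor(0.02 * nchar(part))))
    for (w in windows) {
      if (Biostrings::countPattern(Biostrings::DNAString(part),
                                   Biostrings::DNAString(w),
                                   max.mismatch = mism) > 0L) {
        return(TRUE)
      }
    }
    FALSE
  }
  longest_terminal <- function(side) {
    take <- function(L) {
      if (side == "suffix") substring(consensus, len - L + 1L) else
        substr(consensus, 1L, L)
    }
    if (!occurs(take(min(12L, len)))) return(0L)
    lo <- min(12L, len); hi <- len
    while (lo < hi) {
      mid <- (lo + hi + 1L) %/% 2L
      if (occurs(take(mid))) lo <- mid else hi <- mid - 1L
    }
    lo
  }
  suf <- longest_terminal("suffix")
  pre <- longest_terminal("prefix")
  g_len <- max(suf, pre)
  res <- list(verdict = "ambiguous", genome_identity = g_len / len,
              genome_range = if (suf >= pre) c(len - suf + 1L, len) else
                c(1L, pre),
              l1_hit = NULL)
  if (g_len >= 0.95 * len) {
    res$verdict <- "reference_only"
    return(res)
  }
  rem <- if (suf >= pre) {
    substr(consensus, 1L, len - suf)
  } else {
    substring(consensus, pre + 1L)
  }
  if (nchar(rem) < 8L) {
    res$verdict <- "reference_only"
    return(res)
  }
  genome_part <- substring(consensus, res$genome_range[1L],
                           res$genome_range[2L])
  if (nchar(genome_part) < 12L) return(res)

  hit <- align_to_l1(rem, l1_3prime_polyA, min_identity = min_identity)
  if (is.null(hit)) return(res)
  res$l1_hit <- hit

  if (nchar(genome_part) >= 20L) {
    # the genome-matching part must be unique in the reference
    gp <- Biostrings::DNAString(genome_part)
    mism <- max(1L, as.integer(floor(0.02 * nchar(genome_part))))
    n_occ <- 0L
    for (cn in names(chroms)) {
      subj <- Biostrings::DNAString(chroms[[cn]])
      n_occ <- n_occ +
        Biostrings::countPattern(gp, subj, max.mismatch = mism) +
        Biostrings::countPattern(Biostrings::reverseComplement(gp), subj,
                                 max.mismatch = mism)
      if (n_occ > 1L) break
    }
    if (n_occ == 1L) res$verdict <- "insertion_supported"
  } else if (!is.null(peak)) {
    # a short flank block cannot carry a genome-wide uniqueness test on
    # its own, but the peak it sits in was built from uniquely aligned
    # reads, which already pins the locus; consistency with the locus
    # window suffices
    res$verdict <- "insertion_supported"
  }
  res
}
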