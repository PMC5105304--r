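# Tumor-normal comparison in both directions, in-silico spanning-PCR
# validation of discordant calls, and CN/LOH segment integration for
# normal-only insertions.

#' Partition matched call sets into shared and sample-exclusive calls
#'
#' Calls within `window` bp of a call in the other sample are shared;
#' the rest are tumor-only or normal-only. The partition is disjoint and
#' exhaustive.
#'
#' @param tumor_calls,normal_calls data.frames with chrom, start, end.
#' @param window maximum gap for two calls to be considered the same locus.
#' @return list(tumor_only, normal_only, shared): `shared` carries the
#'   tumor rows with a `matched_normal` index column.
#' @export
compare_call_sets <- function(tumor_calls, normal_calls, window = 200L) {
  gr <- function(df) {
    if (nrow(df) == 0L) {
      return(GenomicRanges::GRanges())
    }
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(df$start, df$end))
  }
  gt <- gr(tumor_calls)
  gn <- gr(normal_calls)
  if (length(gt) == 0L || length(gn) == 0L) {
    shared_t <- rep(FALSE, length(gt))
    shared_n <- rep(FALSE, length(gn))
  } else {
    hits <- GenomicRanges::findOverlaps(gt, gn, maxgap = window)
    shared_t <- seq_along(gt) %in% S4Vectors::queryHits(hits)
    shared_n <- seq_along(gn) %in% S4Vectors::subjectHits(hits)
  }
  list(
    tumor_only = tumor_calls[!shared_t, , drop = FALSE],
    normal_only = normal_calls[!shared_n, , drop = FALSE],
    shared = tumor_calls[shared_t, , drop = FALSE]
  )
}

# unique exact occurrence count of a primer across a genome (both strands)
primer_occurrences <- function(primer, chroms) {
  p <- Biostrings::DNAString(primer)
  rc <- Biostrings::reverseComplement(p)
  n <- 0L
  for (cn in names(chroms)) {
    subj <- Biostrings::DNAString(chroms[[cn]])
    n <- n + Biostrings::countPattern(p, subj) +
      Biostrings::countPattern(rc, subj)
    if (n > 1L) return(n)
  }
  n
}

# scan outward from `from` for a unique primer_flank-mer; dir -1 scans left
# (primer ends near `from`), dir +1 scans right (primer starts near `from`)
find_unique_primer <- function(chroms, chrom, from, dir,
                               primer_flank = 20L, max_shift = 500L) {
  s <- chroms[[chrom]]
  for (shift in 0:max_shift) {
    if (dir < 0) {
      en <- from - shift
      st <- en - primer_flank + 1L
    } else {
      st <- from + shift
      en <- st + primer_flank - 1L
    }
    if (st < 1L || en > nchar(s)) return(NULL)
    primer <- substr(s, st, en)
    if (grepl("N", primer, fixed = TRUE)) next
    if (primer_occurrences(primer, chroms) == 1L) {
      return(list(seq = primer, start = st, end = en))
    }
  }
  NULL
}

# product sizes between two primers on one haplotype sequence (plus strand
# left primer, plus strand right primer), bounded by max_amplicon
haplotype_products <- function(hapseq, left, right, max_amplicon) {
  subj <- Biostrings::DNAString(hapseq)
  ls <- BiocGenerics::start(Biostrings::matchPattern(left, subj))
  rs <- BiocGenerics::start(Biostrings::matchPattern(right, subj))
  if (length(ls) == 0L || length(rs) == 0L) return(integer(0))
  sizes <- integer(0)
  for (l in ls) {
    r <- rs[rs > l]
    if (length(r) == 0L) next
    sz <- (r[1L] + nchar(right) - 1L) - l + 1L
    if (sz <= max_amplicon) sizes <- c(sizes, sz)
  }
  sort(unique(sizes))
}

#' In-silico spanning-PCR validation of a discordant call
#'
#' Unique exact `primer_flank`-mers are picked from the reference on both
#' sides of the putative insertion junction (the desk stand-in for primer
#' design), then every haplotype of both samples is searched for the primer
#' pair and the resulting product sizes are collected. A sample supports
#' the insertion ("productive" filled-site reaction) when it yields a
#' product meaningfully larger than the reference (empty-site) product.
#'
#' @param call one-row data.frame with chrom and a junction position
#'   (`junction_pos`; falls back to `start`).
#' @param blood_sample,tumor_sample `tip_sample` objects.
#' @param reference shared `tip_genome` used for primer design.
#' @param primer_flank primer length.
#' @param max_amplicon maximum product size considered amplifiable.
#' @param primer_offset distance from the junction at which primer search
#'   starts.
#' @return list(status, productive_blood, productive_tumor, empty_size,
#'   sizes_blood, sizes_tumor, primers): `status` is "tested" or
#'   "untested" (no unique primer found).
#' @export
insilico_validate <- function(call, blood_sample, tumor_sample, reference,
                              primer_flank = 20L, max_amplicon = 9000L,
                              primer_offset = 150L) {
  cn <- call$chrom[1L]
  j <- call$junction_pos[1L] %||% call$start[1L]
  if (is.na(j)) j <- call$start[1L]
  chroms <- reference$chromosomes
  left <- find_unique_primer(chroms, cn, j - primer_offset, dir = -1L,
                             primer_flank = primer_flank)
  right <- find_unique_primer(chroms, cn, j + primer_offset, dir = +1L,
                              primer_flank = primer_flank)
  if (is.null(left) || is.null(right)) {
    return(list(status = "untested", productive_blood = NA,
                productive_tumor = NA, empty_size = NA_integer_,
                sizes_blood = integer(0), sizes_tumor = integer(0),
                primers = NULL))
  }
  empty_size <- right$end - left$start + 1L
  sizes_for <- function(sample) {
    out <- integer(0)
    for (hap in sample$haplotypes) {
      if (!cn %in% names(hap$chromosomes)) next
      out <- c(out, haplotype_products(hap$chromosomes[[cn]], left$seq,
                                       right$seq, max_amplicon))
    }
    sort(unique(out))
  }
  sb <- sizes_for(blood_sample)
  st <- sizes_for(tumor_sample)
  filled <- function(sizes) any(sizes > empty_size + 20L)
  list(
    status = "tested",
    productive_blood = filled(sb),
    productive_tumor = filled(st),
    empty_size = empty_size,
    sizes_blood = sb, sizes_tumor = st,
    primers = list(left = left, right = right)
  )
}

#' Annotate normal-only calls with tumor CN/LOH segments
#'
#' @param normal_only_calls data.frame of normal-only calls (chrom,
#'   junction_pos or start).
#' @param segments CN/LOH segment table; validated for consistency.
#' @return calls with `cn` and `loh` columns ("NT" when no segment
#'   overlaps).
#' @export
integrate_cn_loh <- function(normal_only_calls, segments) {
  segments <- validate_segments(segments)
  calls <- normal_only_calls
  n <- nrow(calls)
  calls$cn <- rep("NT", n)
  calls$loh <- rep("NT", n)
  if (n == 0L || nrow(segments) == 0L) return(calls)
  pos <- calls$junction_pos %||% calls$start
  pos[is.na(pos)] <- calls$start[is.na(pos)]
  for (i in seq_len(n)) {
    hit <- which(segments$chrom == calls$chrom[i] &
                   segments$start <= pos[i] & segments$end >= pos[i])
    if (length(hit) > 0L) {
      calls$cn[i] <- as.character(segments$copy_number[hit[1L]])
      calls$loh[i] <- if (segments$loh[hit[1L]]) "Y" else "N"
    }
  }
  calls
}
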