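# Patient pairs: matched blood (constitutional) and tumor genomes derived
# from a shared reference. Insertions are heterozygous (haplotype 1 carries
# them); tumors additionally carry somatic implants and may lose germline
# insertions through deletion (CN 1) or copy-neutral (CN 2) loss of
# heterozygosity.

new_tip_sample <- function(sample_id, haplotypes) {
  structure(list(sample_id = sample_id, haplotypes = haplotypes),
            class = "tip_sample")
}

#' @export
print.tip_sample <- function(x, ...) {
  cat("tip_sample", x$sample_id, "with", length(x$haplotypes),
      "haplotype(s)\n")
  invisible(x)
}

empty_segments <- function() {
  data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    copy_number = integer(0), loh = logical(0), stringsAsFactors = FALSE
  )
}

validate_segments <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0) return(empty_segments())
  stopifnot(all(c("chrom", "start", "end", "copy_number", "loh") %in%
                  names(segments)))
  if (any(segments$copy_number == 1L & !segments$loh)) {
    stop("CN/LOH segments: copy_number == 1 implies loh == TRUE")
  }
  if (!all(segments$copy_number %in% c(1L, 2L))) {
    stop("CN/LOH segments: only copy numbers 1 and 2 are in scope")
  }
  for (cn in unique(segments$chrom)) {
    s <- segments[segments$chrom == cn, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      stop("CN/LOH segments overlap on ", cn)
    }
  }
  segments
}

#' Build a matched blood/tumor patient pair
#'
#' Haplotype 1 of each sample receives the implants (heterozygous); haplotype
#' 2 is the unmodified reference. Somatic insertions go into the tumor only.
#' When `segments` are given, [apply_cn_loh()] is applied to the pair.
#'
#' @param reference shared `tip_genome`.
#' @param patient_id character id.
#' @param insertions TruthInsertion data.frame (rows from
#'   [truth_insertion()]); the `somatic` column routes rows to the tumor.
#' @param segments optional CN/LOH segment table for the tumor
#'   (chrom, start, end, copy_number, loh), reference coordinates.
#' @return a `tip_pair`: list(patient_id, reference, blood, tumor, truth,
#'   segments).
#' @export
build_patient_pair <- function(reference, patient_id, insertions = NULL,
                               segments = NULL) {
  if (is.null(insertions)) insertions <- empty_implants()
  germline <- insertions[!insertions$somatic, , drop = FALSE]
  somatic <- insertions[insertions$somatic, , drop = FALSE]

  # right-to-left per chromosome, so every splice coordinate is still a
  # reference coordinate when it is applied
  implant_all <- function(genome, rows) {
    if (nrow(rows) > 0) {
      rows <- rows[order(rows$chrom, -rows$tsd_start), , drop = FALSE]
      for (i in seq_len(nrow(rows))) {
        genome <- implant_insertion(genome, rows[i, , drop = FALSE])
      }
    }
    genome
  }

  blood <- new_tip_sample(
    paste0(patient_id, "_blood"),
    list(h1 = implant_all(reference, germline), h2 = reference)
  )
  tumor <- new_tip_sample(
    paste0(patient_id, "_tumor"),
    list(h1 = implant_all(reference, rbind(germline, somatic)),
         h2 = reference)
  )
  truth <- rbind(germline, somatic)
  truth$cn <- rep(NA_integer_, nrow(truth))
  truth$loh <- rep(NA, nrow(truth))
  pair <- structure(
    list(patient_id = patient_id, reference = reference,
         blood = blood, tumor = tumor, truth = truth,
         segments = empty_segments()),
    class = "tip_pair"
  )
  if (!is.null(segments) && nrow(segments) > 0) {
    pair <- apply_cn_loh(pair, segments)
  }
  pair
}

#' Apply tumor CN/LOH segments to a patient pair
#'
#' For every heterozygous germline implant overlapped by an LOH segment, the
#' tumor loses the insertion-carrying allele: under copy-neutral LOH (CN 2)
#' the carrier haplotype segment is replaced by the insertion-free
#' haplotype's copy; under a deletion (CN 1) the carrier haplotype segment is
#' excised outright. Affected truth rows are marked `blood_only_loss` and
#' annotated with the segment's CN/LOH.
#'
#' @param pair a `tip_pair`.
#' @param segments CN/LOH table (chrom, start, end, copy_number, loh) in
#'   reference coordinates.
#' @return the modified `tip_pair` (tumor genome rebuilt, `segments` stored).
#' @export
apply_cn_loh <- function(pair, segments) {
  stopifnot(inherits(pair, "tip_pair"))
  segments <- validate_segments(segments)
  truth <- pair$truth
  if (nrow(segments) == 0) {
    pair$segments <- segments
    return(pair)
  }

  overlaps_segment <- function(chrom, lo, hi) {
    segments$chrom == chrom & segments$start <= hi & segments$end >= lo
  }

  lost <- logical(nrow(truth))
  cn_col <- truth$cn
  loh_col <- truth$loh
  if (nrow(truth) > 0) {
    for (i in seq_len(nrow(truth))) {
      hit <- which(overlaps_segment(truth$chrom[i], truth$tsd_start[i],
                                    truth$tsd_end[i]))
      if (length(hit) == 0) next
      seg <- segments[hit[1L], ]
      if (truth$somatic[i] && seg$copy_number == 1L) {
        stop(
          "apply_cn_loh: CN 1 segment overlaps a tumor-specific implant at ",
          truth$chrom[i], ":", truth$tsd_start[i]
        )
      }
      if (!truth$somatic[i] && seg$loh) {
        lost[i] <- TRUE
        cn_col[i] <- seg$copy_number
        loh_col[i] <- TRUE
      }
    }
  }

  # rebuild tumor haplotype 1: reference + surviving germline + somatic,
  # right-to-left so splice coordinates stay in the reference frame
  keep <- truth[!lost | truth$somatic, , drop = FALSE]
  keep <- keep[order(keep$chrom, -keep$tsd_start), , drop = FALSE]
  h1 <- pair$reference
  if (nrow(keep) > 0) {
    for (i in seq_len(nrow(keep))) {
      h1 <- implant_insertion(h1, keep[i, , drop = FALSE])
    }
  }

  # CN 1 deletions excise the carrier-haplotype segment (reference
  # coordinates mapped through surviving implants on the same chromosome)
  del <- segments[segments$copy_number == 1L, , drop = FALSE]
  if (nrow(del) > 0) {
    for (i in seq_len(nrow(del))) {
      cn <- del$chrom[i]
      if (!cn %in% names(h1$chromosomes)) next
      # implant records live in haplotype coordinates; recover their
      # reference coordinates by removing the cumulative upstream growth
      imp <- h1$implants[h1$implants$chrom == cn, , drop = FALSE]
      imp <- imp[order(imp$tsd_end), , drop = FALSE]
      grown <- if (nrow(imp)) {
        cumsum(c(0L, imp$ins_size))[seq_len(nrow(imp))]
      } else {
        integer(0)
      }
      ref_end <- imp$tsd_end - grown
      ref_start <- imp$tsd_start - grown
      offset_at <- function(p) sum(imp$ins_size[ref_end < p])
      inside <- nrow(imp) > 0 &&
        any(ref_start >= del$start[i] & ref_end <= del$end[i])
      if (inside) {
        stop("apply_cn_loh: CN 1 segment still contains an implant after ",
             "LOH resolution at ", cn, ":", del$start[i])
      }
      s <- max(1L, del$start[i] + offset_at(del$start[i]))
      e <- min(nchar(h1$chromosomes[[cn]]),
               del$end[i] + offset_at(del$end[i]))
      h1 <- delete_interval(h1, cn, s, e)
    }
  }

  truth$blood_only_loss <- lost
  truth$cn <- cn_col
  truth$loh <- loh_col
  pair$truth <- truth
  pair$tumor <- new_tip_sample(paste0(pair$patient_id, "_tumor"),
                               list(h1 = h1, h2 = pair$reference))
  pair$segments <- segments
  pair
}
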