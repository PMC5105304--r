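# Implanting L1 insertions with TPRT hallmarks into a genome.
#
# Inserted allele structure on the plus strand of the modified chromosome
# (for an insertion on strand s):
#
#   ... flank5 | TSD | body(s) | TSD | flank3 ...
#
# where body(+) = revcomp(5' inverted segment) + 3' element portion + polyA
# and body(-) = revcomp(body(+)). The target site duplication arises by
# duplicating the reference interval [tsd_start, tsd_end] spanned by the two
# junction coordinates, so tsd_length == |junction5 - junction3| + 1 by
# construction.

empty_implants <- function() {
  data.frame(
    id = character(0), chrom = character(0),
    junction5 = integer(0), junction3 = integer(0), strand = character(0),
    element_length = integer(0), inversion_length = integer(0),
    polyA_length = integer(0), tsd_length = integer(0),
    somatic = logical(0), blood_only_loss = logical(0),
    partial = logical(0),
    tsd_start = integer(0), tsd_end = integer(0),
    ins_size = integer(0),
    hap_junction = integer(0), direction = integer(0),
    stringsAsFactors = FALSE
  )
}

#' Construct and validate a truth insertion specification
#'
#' @param chrom chromosome name.
#' @param junction5,junction3 1-based genomic junction coordinates; both lie
#'   inside the duplicated interval, so the TSD length is
#'   `abs(junction5 - junction3) + 1`.
#' @param strand "+" or "-".
#' @param element_length total inserted element length in bp, inversion
#'   included, polyA excluded.
#' @param inversion_length length of the 5' segment present in inverted
#'   orientation (0 for none).
#' @param polyA_length polyA tail length in bp.
#' @param tsd_length target site duplication length; must equal
#'   `abs(junction5 - junction3) + 1`.
#' @param somatic present in tumor only.
#' @param blood_only_loss germline insertion lost from the tumor (set by
#'   [apply_cn_loh()], not normally by hand).
#' @param partial marks presets whose 5' end the source table left
#'   uncharacterized; lengths are configured defaults.
#' @param id identifier.
#' @return one-row data.frame (a TruthInsertion).
#' @export
truth_insertion <- function(chrom, junction5, junction3, strand,
                            element_length, inversion_length = 0L,
                            polyA_length = 20L,
                            tsd_length = abs(junction5 - junction3) + 1L,
                            somatic = FALSE, blood_only_loss = FALSE,
                            partial = FALSE, id = NA_character_) {
  if (tsd_length != abs(junction5 - junction3) + 1L) {
    stop(
      "truth_insertion: invariant violated: tsd_length (", tsd_length,
      ") != |junction5 - junction3| + 1 (", abs(junction5 - junction3) + 1L, ")"
    )
  }
  if (!(inversion_length >= 0L && inversion_length < element_length)) {
    stop(
      "truth_insertion: invariant violated: need 0 <= inversion_length < ",
      "element_length, got inversion_length=", inversion_length,
      ", element_length=", element_length
    )
  }
  if (element_length > L1_CONSENSUS_LENGTH) {
    stop(
      "truth_insertion: invariant violated: element_length (", element_length,
      ") exceeds consensus length (", L1_CONSENSUS_LENGTH, ")"
    )
  }
  if (!strand %in% c("+", "-")) stop("truth_insertion: strand must be + or -")
  data.frame(
    id = id, chrom = chrom,
    junction5 = as.integer(junction5), junction3 = as.integer(junction3),
    strand = strand,
    element_length = as.integer(element_length),
    inversion_length = as.integer(inversion_length),
    polyA_length = as.integer(polyA_length),
    tsd_length = as.integer(tsd_length),
    somatic = somatic, blood_only_loss = blood_only_loss, partial = partial,
    tsd_start = min(junction5, junction3),
    tsd_end = max(junction5, junction3),
    ins_size = as.integer(element_length + polyA_length + tsd_length),
    hap_junction = NA_integer_, direction = NA_integer_,
    stringsAsFactors = FALSE
  )
}

# Plus-strand body of the inserted sequence (element as it appears for a
# "+" insertion, before any whole-body reverse complement for "-").
build_insert_body <- function(element_length, inversion_length, polyA_length) {
  l1 <- l1_consensus()
  L <- L1_CONSENSUS_LENGTH
  e3 <- element_length - inversion_length
  seg3 <- substr(l1$sequence, L - e3 + 1L, L)
  seg_inv <- if (inversion_length > 0L) {
    revcomp(substr(l1$sequence, L - e3 - inversion_length + 1L, L - e3))
  } else {
    ""
  }
  paste0(seg_inv, seg3, strrep("A", polyA_length))
}

#' Implant an L1 insertion into a genome
#'
#' Splices the insertion allele (TSD-flanked, strand-oriented, polyA-tailed)
#' into the chromosome, growing it by `element_length + polyA_length +
#' tsd_length`. Coordinates of annotation and previously implanted rows to
#' the right of the site are shifted accordingly, so implants can be applied
#' in any order as long as their target sites do not intersect.
#'
#' @param genome a `tip_genome`.
#' @param ins a TruthInsertion row from [truth_insertion()].
#' @return the modified `tip_genome`, with the implant recorded in
#'   `$implants` (including the realized haplotype coordinate of the L1 3'
#'   junction used by the read simulator).
#' @export
implant_insertion <- function(genome, ins) {
  stopifnot(inherits(genome, "tip_genome"), nrow(ins) == 1L)
  cn <- ins$chrom
  if (!cn %in% names(genome$chromosomes)) {
    stop("implant_insertion: unknown chromosome ", cn)
  }
  s <- genome$chromosomes[[cn]]
  tsd_start <- ins$tsd_start
  tsd_end <- ins$tsd_end
  if (tsd_start < 1L || tsd_end > nchar(s)) {
    stop("implant_insertion: target site out of chromosome bounds")
  }
  # target site must not intersect fixed L1 copies or other implants
  ann <- genome$l1_annotation
  if (nrow(ann) > 0 &&
      any(ann$chrom == cn & ann$start <= tsd_end & ann$end >= tsd_start)) {
    stop("implant_insertion: target site intersects fixed L1 annotation")
  }
  imp <- genome$implants
  if (nrow(imp) > 0 &&
      any(imp$chrom == cn & imp$tsd_start <= tsd_end &
            imp$tsd_end >= tsd_start)) {
    stop("implant_insertion: target site intersects an existing implant")
  }

  body <- build_insert_body(ins$element_length, ins$inversion_length,
                            ins$polyA_length)
  if (ins$strand == "-") body <- revcomp(body)
  genome$chromosomes[[cn]] <- paste0(
    substr(s, 1L, tsd_end), body, substr(s, tsd_start, nchar(s))
  )
  shift <- nchar(body) + (tsd_end - tsd_start + 1L)  # == ins$ins_size

  # shift features strictly to the right of the insertion point
  if (nrow(ann) > 0) {
    right <- ann$chrom == cn & ann$start > tsd_end
    genome$l1_annotation$start[right] <- ann$start[right] + shift
    genome$l1_annotation$end[right] <- ann$end[right] + shift
  }
  if (nrow(imp) > 0) {
    right <- imp$chrom == cn & imp$tsd_start > tsd_end
    for (col in c("tsd_start", "tsd_end", "hap_junction")) {
      genome$implants[[col]][right] <- imp[[col]][right] + shift
    }
  }

  # record only the implant-schema columns (callers may pass decorated rows)
  rec <- ins[, names(empty_implants()), drop = FALSE]
  if (ins$strand == "+") {
    # last polyA base; downstream flank (second TSD copy onwards) to the right
    rec$hap_junction <- tsd_end + nchar(body)
    rec$direction <- 1L
  } else {
    # first polyT base on the plus strand; flank runs leftward
    rec$hap_junction <- tsd_end + 1L
    rec$direction <- -1L
  }
  genome$implants <- rbind(genome$implants, rec)
  genome
}

#' Reconstruct the implanted allele and its flanks at a known locus
#'
#' Builds, from the *pre-insertion* genome and a truth specification, the
#' local modified-allele sequence together with the two pre-insertion flank
#' sequences that [characterize_insertion()] expects: `flank5` ends with the
#' original target-site copy and `flank3` begins with it.
#'
#' @param reference pre-insertion `tip_genome`.
#' @param ins TruthInsertion row.
#' @param flank flank length to include on each side.
#' @return list(allele, flank5, flank3).
#' @export
insertion_locus <- function(reference, ins, flank = 400L) {
  s <- reference$chromosomes[[ins$chrom]]
  a <- max(1L, ins$tsd_start - flank)
  b <- min(nchar(s), ins$tsd_end + flank)
  flank5 <- substr(s, a, ins$tsd_end)
  flank3 <- substr(s, ins$tsd_start, b)
  body <- build_insert_body(ins$element_length, ins$inversion_length,
                            ins$polyA_length)
  if (ins$strand == "-") body <- revcomp(body)
  list(
    allele = paste0(flank5, body, flank3),
    flank5 = flank5,
    flank3 = flank3
  )
}

# Excise [start, end] from a chromosome (used for copy-number-1 loss).
# Features wholly inside the interval are dropped; features to the right
# shift left.
delete_interval <- function(genome, chrom, start, end) {
  s <- genome$chromosomes[[chrom]]
  stopifnot(start >= 1L, end <= nchar(s), start <= end)
  w <- end - start + 1L
  genome$chromosomes[[chrom]] <-
    paste0(substr(s, 1L, start - 1L), substr(s, end + 1L, nchar(s)))
  ann <- genome$l1_annotation
  if (nrow(ann) > 0) {
    sel <- ann$chrom == chrom
    if (any(sel & ann$start >= start & ann$end <= end)) {
      keep <- !(sel & ann$start >= start & ann$end <= end)
      ann <- ann[keep, , drop = FALSE]
      sel <- ann$chrom == chrom
    }
    if (any(sel & ann$start <= end & ann$end >= start)) {
      # partial overlap of a fixed element would leave a broken copy
      stop("delete_interval: deletion partially overlaps an L1 annotation")
    }
    right <- sel & ann$start > end
    ann$start[right] <- ann$start[right] - w
    ann$end[right] <- ann$end[right] - w
    genome$l1_annotation <- ann
  }
  imp <- genome$implants
  if (nrow(imp) > 0) {
    inside <- imp$chrom == chrom & imp$tsd_start >= start & imp$tsd_end <= end
    imp <- imp[!inside, , drop = FALSE]
    right <- imp$chrom == chrom & imp$tsd_start > end
    for (col in c("tsd_start", "tsd_end", "hap_junction")) {
      imp[[col]][right] <- imp[[col]][right] - w
    }
    genome$implants <- imp
  }
  genome$deletions <- rbind(
    genome$deletions,
    data.frame(chrom = chrom, start = start, end = end,
               stringsAsFactors = FALSE)
  )
  genome
}
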