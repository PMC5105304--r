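# TPRT hallmark annotation: target site duplication, element length, 5'
# inversion, polyA tail, strand, and gene context for validated insertions.

#' Target site duplication length from the two junction coordinates
#'
#' Both junction coordinates lie inside the duplicated interval, so the TSD
#' spans `abs(junction5 - junction3) + 1` bp.
#'
#' @param junction5,junction3 1-based genomic junction coordinates.
#' @return integer TSD length (vectorized).
#' @export
measure_tsd <- function(junction5, junction3) {
  stopifnot(all(junction5 > 0), all(junction3 > 0))
  as.integer(abs(junction5 - junction3) + 1L)
}

# longest k with suffix(a, k) == prefix(b, k)
longest_dup <- function(a, b, max_k = 200L) {
  kmax <- min(nchar(a), nchar(b), max_k)
  for (k in rev(seq_len(kmax))) {
    if (substring(a, nchar(a) - k + 1L) == substr(b, 1L, k)) return(k)
  }
  0L
}

#' Measure TPRT hallmarks of an insertion allele
#'
#' Given the modified-locus sequence and the two pre-insertion flanks
#' (`flank5` ending at, and `flank3` beginning with, the original
#' target-site copy), detects the TSD as the longest exactly duplicated
#' flank suffix/prefix pair, strips the polyA (or leading polyT) tail,
#' and decomposes the element against the consensus: the 3' portion must
#' match the consensus 3' terminus in forward orientation and any remaining
#' 5' portion must match the adjacent upstream consensus segment in
#' inverted orientation (twin-priming signature).
#'
#' @param allele_sequence sequence of the inserted-allele locus
#'   (flank5 + insertion body + flank3).
#' @param flank5,flank3 pre-insertion flanking sequences as above.
#' @param l1_consensus element consensus string.
#' @param min_tail minimum mononucleotide run treated as a tail.
#' @return list(strand, element_length, inversion_length, polyA_length,
#'   tsd_length).
#' @export
characterize_insertion <- function(allele_sequence, flank5, flank3,
                                   l1_consensus = NULL, min_tail = 5L) {
  if (is.null(l1_consensus)) l1_consensus <- .l1_default_sequence()
  if (substr(allele_sequence, 1L, nchar(flank5)) != flank5) {
    stop("characterize_insertion: allele does not start with flank5")
  }
  if (substring(allele_sequence,
                nchar(allele_sequence) - nchar(flank3) + 1L) != flank3) {
    stop("characterize_insertion: allele does not end with flank3")
  }
  tsd_length <- longest_dup(flank5, flank3)
  body <- substr(allele_sequence, nchar(flank5) + 1L,
                 nchar(allele_sequence) - nchar(flank3))
  if (nchar(body) == 0L) {
    stop("characterize_insertion: empty insertion body")
  }

  # strand from the tail: polyA at the 3' end (plus) or polyT at the 5'
  # end of the plus-strand body (minus)
  ch <- strsplit(body, "", fixed = TRUE)[[1]]
  trail_a <- {
    r <- rle(rev(ch) == "A")
    if (r$values[1L]) r$lengths[1L] else 0L
  }
  lead_t <- {
    r <- rle(ch == "T")
    if (r$values[1L]) r$lengths[1L] else 0L
  }
  if (max(trail_a, lead_t) < min_tail) {
    stop("characterize_insertion: not an L1 insertion (no polyA/polyT tail)")
  }
  strand <- if (trail_a >= lead_t) "+" else "-"
  if (strand == "-") body <- revcomp(body)
  polyA_length <- {
    ch2 <- strsplit(body, "", fixed = TRUE)[[1]]
    r <- rle(rev(ch2) == "A")
    if (r$values[1L]) r$lengths[1L] else 0L
  }
  element <- substr(body, 1L, nchar(body) - polyA_length)
  elen <- nchar(element)
  if (elen == 0L) stop("characterize_insertion: no element sequence")

  # split into forward 3' portion and inverted 5' portion
  L <- nchar(l1_consensus)
  lcs <- common_suffix_len(element, l1_consensus)
  if (lcs < min(8L, elen)) {
    stop("characterize_insertion: not an L1 insertion (3' end does not ",
         "match the consensus)")
  }
  inversion_length <- NA_integer_
  for (k in rev(seq_len(lcs))) {
    inv <- elen - k
    if (inv == 0L) {
      inversion_length <- 0L
      break
    }
    lo <- L - k - inv + 1L
    if (lo < 1L) next
    if (substr(element, 1L, inv) ==
        revcomp(substr(l1_consensus, lo, L - k))) {
      inversion_length <- inv
      break
    }
  }
  if (is.na(inversion_length)) {
    stop("characterize_insertion: not an L1 insertion (5' portion matches ",
         "neither orientation of the consensus)")
  }
  list(
    strand = strand,
    element_length = elen,
    inversion_length = inversion_length,
    polyA_length = as.integer(polyA_length),
    tsd_length = as.integer(tsd_length)
  )
}

#' Gene context of an insertion position
#'
#' @param insertion list or one-row data.frame with `chrom` and a position
#'   (`pos`, `junction_pos`, or `tsd_start`).
#' @param genes data.frame(gene, chrom, start, end, strand).
#' @param exons data.frame(gene, chrom, start, end); exon blocks of the
#'   genes.
#' @return list(gene, feature, distance): feature is "exon", "intron" or
#'   "intergenic"; distance is 0 inside a gene, else bp to the nearest gene
#'   (Inf when `genes` is empty).
#' @export
gene_overlap <- function(insertion, genes, exons = NULL) {
  if (is.null(genes) || !all(c("gene", "chrom", "start", "end") %in%
                               names(genes))) {
    stop("gene_overlap: malformed gene annotation (need gene, chrom, ",
         "start, end)")
  }
  pos <- insertion$pos %||% insertion$junction_pos %||% insertion$tsd_start
  if (is.null(pos) || is.na(pos)) stop("gene_overlap: no position")
  cn <- insertion$chrom
  g <- genes[genes$chrom == cn & genes$start <= pos & genes$end >= pos, ,
             drop = FALSE]
  if (nrow(g) > 0L) {
    gene <- g$gene[1L]
    feature <- "intron"
    if (!is.null(exons)) {
      e <- exons[exons$gene == gene & exons$start <= pos &
                   exons$end >= pos, , drop = FALSE]
      if (nrow(e) > 0L) feature <- "exon"
    }
    return(list(gene = gene, feature = feature, distance = 0L))
  }
  same <- genes[genes$chrom == cn, , drop = FALSE]
  if (nrow(same) == 0L) {
    return(list(gene = NA_character_, feature = "intergenic",
                distance = Inf))
  }
  d <- pmax(0L, pmax(same$start - pos, pos - same$end))
  i <- which.min(d)
  list(gene = same$gene[i], feature = "intergenic", distance = d[i])
}

#' Render the validated-insertion report
#'
#' One row per annotated insertion in the source table's column order
#' (sample, chromosome, junctions, strand, element length, TSD, gene, CN,
#' LOH) plus provenance columns, with blood-specific rows before
#' tumor-specific rows. Deterministic: re-rendering identical input yields
#' a byte-identical table.
#'
#' @param annotated data.frame of annotated insertions; must carry
#'   `sample_id`, `chrom`, `junction5`, `junction3`, `strand`,
#'   `element_length`, `tsd_length` and a logical `somatic` column;
#'   optional `inversion_length`, `polyA_length`, `gene`, `cn`, `loh`,
#'   `validation`.
#' @return data.frame in report column order.
#' @export
render_report <- function(annotated) {
  cols <- c("sample_id", "chrom", "junction5", "junction3", "strand",
            "element_length", "tsd_length", "gene", "cn", "loh",
            "inversion_length", "polyA_length", "validation", "category")
  if (nrow(annotated) == 0L) {
    out <- as.data.frame(
      stats::setNames(rep(list(character(0)), length(cols)), cols),
      stringsAsFactors = FALSE
    )
    return(out)
  }
  a <- annotated
  for (col in c("gene", "cn", "loh", "validation")) {
    if (!col %in% names(a)) a[[col]] <- NA_character_
  }
  for (col in c("inversion_length", "polyA_length")) {
    if (!col %in% names(a)) a[[col]] <- NA_integer_
  }
  a$category <- ifelse(a$somatic, "tumor_specific", "blood_specific")
  a <- a[order(a$category != "blood_specific", a$sample_id, a$chrom,
               pmin(a$junction5, a$junction3)), , drop = FALSE]
  rownames(a) <- NULL
  a[, cols]
}
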