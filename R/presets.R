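# The validated-insertion preset panel: eleven blood-specific germline
# insertions across six patients (eight fully sequenced, three with an
# uncharacterized 5' end) and one tumor-specific somatic insertion with a
# 5' inversion, together with their printed junction coordinates, element
# and TSD lengths, gene context and tumor CN/LOH state. Printed coordinates
# are folded onto toy chromosomes with their pairwise offsets preserved.

.table2_rows <- function() {
  data.frame(
    sample_id = c("750", "750", "772", "832", "847", "847",
                  "897", "897", "897", "897", "922", "083"),
    chrom = c("chr5", "chr13", "chr14", "chr10", "chr11", "chr11",
              "chr8", "chr8", "chr13", "chr14", "chr11", "chr17"),
    printed_junction5 = c(NA, 50488000, 33209876, 31557469, 33626714, NA,
                          24982467, 119790870, 85238154, NA, 33626714,
                          47881841),
    printed_junction3 = c(34495746, 50487984, 33209888, 31557476,
                          33626699, 94317493, 24982461, 119790884,
                          85238150, 30220577, 33626699, 47881832),
    strand = c("+", "+", "-", "-", "+", "-", "-", "-", "-", "-", "+", "+"),
    printed_element_length = c(NA, 4162, 5422, 6059, 1281, NA,
                               2845, 965, 684, NA, 1281, 1839),
    printed_tsd_length = c(NA, 17, 13, 8, 16, NA, 7, 15, 5, NA, 16, 10),
    inversion_length = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 662L),
    gene = c(".", "GUCY1B2", "NPAS3", ".", "KIAA1549L", ".",
             ".", "SAMD12AS1", ".", "SCFD1", "KIAA1549L", "."),
    cn = c("1", "1", "1", "1", "1", "1", "2", "2", "1", "2", "1", "NT"),
    loh = c("Y", "Y", "Y", "Y", "Y", "Y", "Y", "Y", "Y", "Y", "Y", "NT"),
    somatic = c(rep(FALSE, 11), TRUE),
    stringsAsFactors = FALSE
  )
}

# fold a printed coordinate onto a toy chromosome of length chrom_length,
# keeping `margin` clear at both ends
fold_coordinate <- function(printed, chrom_length, margin) {
  usable <- chrom_length - 2L * margin
  as.integer(((printed - 1) %% usable) + margin)
}

#' Validated-insertion presets mapped onto synthetic chromosomes
#'
#' Returns one TruthInsertion per preset row: 11 blood-specific (8 fully
#' sequenced, 3 flagged `partial` whose 5' end was never characterized and
#' whose element/TSD lengths are configured defaults) and 1 tumor-specific
#' somatic insertion carrying a 662 bp 5' inversion. Printed junction
#' coordinates are preserved modulo the toy chromosome length, so the
#' printed TSD arithmetic survives the mapping exactly.
#'
#' @param chrom_length toy chromosome length the printed coordinates are
#'   folded onto.
#' @param margin distance kept clear at chromosome ends.
#' @param default_element_length,default_tsd_length,polyA_length configured
#'   values for quantities the source left unstated.
#' @return data.frame of TruthInsertion rows with additional columns
#'   `sample_id`, `gene`, `cn`, `loh`, `printed_junction5`,
#'   `printed_junction3`, `printed_element_length`, `printed_tsd_length`.
#' @export
table2_presets <- function(chrom_length = 120000L, margin = 8000L,
                           default_element_length = 3000L,
                           default_tsd_length = 15L,
                           polyA_length = 20L) {
  tab <- .table2_rows()
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    partial <- is.na(r$printed_junction5)
    base <- min(r$printed_junction5, r$printed_junction3, na.rm = TRUE)
    pos <- fold_coordinate(base, chrom_length, margin)
    if (partial) {
      j3 <- pos
      j5 <- pos + default_tsd_length - 1L
      elen <- default_element_length
      tsd <- default_tsd_length
    } else {
      j5 <- pos + (r$printed_junction5 - base)
      j3 <- pos + (r$printed_junction3 - base)
      elen <- r$printed_element_length
      tsd <- r$printed_tsd_length
    }
    ins <- truth_insertion(
      chrom = r$chrom, junction5 = j5, junction3 = j3, strand = r$strand,
      element_length = elen, inversion_length = r$inversion_length,
      polyA_length = polyA_length, tsd_length = tsd,
      somatic = r$somatic, partial = partial,
      id = sprintf("%s_%s_%d", r$sample_id, r$chrom, j3)
    )
    ins$sample_id <- r$sample_id
    ins$gene <- r$gene
    ins$cn <- r$cn
    ins$loh <- r$loh
    ins$printed_junction5 <- r$printed_junction5
    ins$printed_junction3 <- r$printed_junction3
    ins$printed_element_length <- r$printed_element_length
    ins$printed_tsd_length <- r$printed_tsd_length
    out[[i]] <- ins
  }
  do.call(rbind, out)
}

# toy gene models (gene spanning the insertion, two terminal exons) for the
# named preset genes; everything else stays intergenic
preset_gene_annotation <- function(presets, chrom_length = 120000L) {
  named <- presets[presets$gene != ".", , drop = FALSE]
  named <- named[!duplicated(named$gene), , drop = FALSE]
  if (nrow(named) == 0L) {
    return(list(genes = data.frame(gene = character(0), chrom = character(0),
                                   start = integer(0), end = integer(0),
                                   strand = character(0),
                                   stringsAsFactors = FALSE),
                exons = data.frame(gene = character(0), chrom = character(0),
                                   start = integer(0), end = integer(0),
                                   stringsAsFactors = FALSE)))
  }
  mid <- (named$tsd_start + named$tsd_end) %/% 2L
  genes <- data.frame(
    gene = named$gene, chrom = named$chrom,
    start = pmax(1L, mid - 5000L), end = pmin(chrom_length, mid + 5000L),
    strand = "+", stringsAsFactors = FALSE
  )
  exons <- rbind(
    data.frame(gene = genes$gene, chrom = genes$chrom,
               start = genes$start, end = genes$start + 400L,
               stringsAsFactors = FALSE),
    data.frame(gene = genes$gene, chrom = genes$chrom,
               start = genes$end - 400L, end = genes$end,
               stringsAsFactors = FALSE)
  )
  list(genes = genes, exons = exons)
}

# per-patient tumor CN/LOH segments reproducing the printed CN/LOH states;
# the chr8 copy-neutral LOH spans the whole chromosome
preset_segments <- function(presets, chrom_length = 120000L,
                            half_width = 10000L) {
  segs <- list()
  germ <- presets[!presets$somatic, , drop = FALSE]
  for (pid in unique(germ$sample_id)) {
    rows <- germ[germ$sample_id == pid, , drop = FALSE]
    whole <- rows$sample_id == "897" & rows$chrom == "chr8"
    part <- rows[!whole, , drop = FALSE]
    s <- data.frame(
      sample_id = pid,
      chrom = part$chrom,
      start = pmax(1L, part$tsd_start - half_width),
      end = pmin(chrom_length, part$tsd_end + half_width),
      copy_number = as.integer(part$cn),
      loh = part$loh == "Y",
      stringsAsFactors = FALSE
    )
    if (any(whole)) {
      s <- rbind(s, data.frame(
        sample_id = pid, chrom = "chr8", start = 1L, end = chrom_length,
        copy_number = 2L, loh = TRUE, stringsAsFactors = FALSE
      ))
    }
    segs[[pid]] <- s
  }
  do.call(rbind, segs)
}

TABLE2_PATIENTS <- c("714", "750", "772", "832", "847", "897", "922",
                     "007", "023", "083")
TABLE2_CHROMS <- c("chr5", "chr8", "chr10", "chr11", "chr13", "chr14",
                   "chr17")

#' Build the full preset cohort
#'
#' Seven primary-pair and three secondary-pair patients sharing one
#' synthetic reference (seven 120 kb chromosomes, one fixed L1 copy each).
#' Every blood-specific preset is implanted heterozygously into the blood
#' genome of its patient; matching CN/LOH segments remove each from the
#' tumor; the somatic preset goes into patient 083's tumor only.
#'
#' @param seed master seed.
#' @param chrom_length toy chromosome length.
#' @param n_fixed_l1 fixed L1 copies in the shared reference.
#' @param presets preset table; defaults to [table2_presets()].
#' @return list(reference, patients (named list of `tip_pair`), presets,
#'   genes, exons, segments).
#' @export
build_table2_cohort <- function(seed, chrom_length = 120000L,
                                n_fixed_l1 = 7L,
                                presets = table2_presets(chrom_length)) {
  chrom_lengths <- stats::setNames(rep(chrom_length, length(TABLE2_CHROMS)),
                                   TABLE2_CHROMS)
  avoid <- data.frame(chrom = presets$chrom, start = presets$tsd_start,
                      end = presets$tsd_end, stringsAsFactors = FALSE)
  reference <- build_reference(derive_seed(seed, "reference"),
                               chrom_lengths, n_fixed_l1, avoid = avoid)
  ganno <- preset_gene_annotation(presets, chrom_length)
  segments <- preset_segments(presets, chrom_length)
  patients <- list()
  for (pid in TABLE2_PATIENTS) {
    ins <- presets[presets$sample_id == pid, , drop = FALSE]
    segs <- segments[segments$sample_id == pid,
                     c("chrom", "start", "end", "copy_number", "loh"),
                     drop = FALSE]
    patients[[pid]] <- build_patient_pair(
      reference, pid,
      insertions = if (nrow(ins)) ins else NULL,
      segments = if (nrow(segs)) segs else NULL
    )
  }
  list(reference = reference, patients = patients, presets = presets,
       genes = ganno$genes, exons = ganno$exons, segments = segments)
}
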