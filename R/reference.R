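# Reference genome construction. A `tip_genome` is a plain list:
#   chromosomes   named character vector of sequences
#   l1_annotation data.frame(chrom, start, end, strand, id) of fixed L1
#                 copies (1-based inclusive; interval covers element + tail)
#   implants      data.frame of implanted insertions (empty for a reference)
#   deletions     data.frame(chrom, start, end) of excised segments
# Coordinates of annotation/implant rows always refer to the current
# sequence of the object they live on.

new_tip_genome <- function(chromosomes,
                           l1_annotation = empty_l1_annotation(),
                           implants = empty_implants(),
                           deletions = empty_deletions()) {
  structure(
    list(
      chromosomes = chromosomes,
      l1_annotation = l1_annotation,
      implants = implants,
      deletions = deletions
    ),
    class = "tip_genome"
  )
}

empty_l1_annotation <- function() {
  data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), id = character(0), stringsAsFactors = FALSE
  )
}

empty_deletions <- function() {
  data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    stringsAsFactors = FALSE
  )
}

#' @export
print.tip_genome <- function(x, ...) {
  cat(
    "tip_genome:", length(x$chromosomes), "chromosome(s),",
    sum(nchar(x$chromosomes)), "bp,",
    nrow(x$l1_annotation), "fixed L1 cop(ies),",
    nrow(x$implants), "implant(s)\n"
  )
  invisible(x)
}

#' Build a synthetic reference genome with fixed L1 copies
#'
#' Generates random AT-biased chromosomes and splices in `n_fixed_l1`
#' full-length L1 consensus copies (element + polyA tail) on random strands
#' at uniformly drawn, non-overlapping positions. The annotated interval
#' covers element plus tail, so masking the annotation removes every
#' amplifiable L1 base from the reference. Deterministic for a fixed seed.
#'
#' @param seed integer seed.
#' @param chrom_lengths named integer vector of pre-insertion chromosome
#'   lengths.
#' @param n_fixed_l1 number of fixed L1 copies to place across the genome.
#' @param avoid optional data.frame(chrom, start, end) of intervals
#'   (pre-insertion coordinates) that placements must not come within
#'   `avoid_pad` bp of — used to keep fixed copies clear of planned implant
#'   sites.
#' @param avoid_pad padding around `avoid` intervals.
#' @param margin minimum distance of a placement from either chromosome end.
#' @return a `tip_genome`.
#' @export
build_reference <- function(seed, chrom_lengths, n_fixed_l1,
                            avoid = NULL, avoid_pad = 12000L,
                            margin = 5000L) {
  stopifnot(all(chrom_lengths > 0), n_fixed_l1 >= 0)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  l1 <- l1_consensus()
  block_plus <- paste0(l1$sequence, strrep("A", L1_FIXED_POLYA))
  block_len <- nchar(block_plus)

  withr::with_seed(seed, {
    chroms <- vapply(chrom_lengths, function(n) random_dna(n), character(1))
    names(chroms) <- names(chrom_lengths)

    ann <- empty_l1_annotation()
    if (n_fixed_l1 > 0) {
      # spread copies across chromosomes round-robin, positions uniform
      target_chrom <- rep_len(names(chroms), n_fixed_l1)
      placements <- list()
      for (i in seq_len(n_fixed_l1)) {
        cn <- target_chrom[[i]]
        L <- chrom_lengths[[cn]]
        ok <- FALSE
        for (try in seq_len(1000L)) {
          pos <- sample.int(L - 2L * margin, 1L) + margin
          clash <- FALSE
          for (p in placements) {
            if (p$chrom == cn && abs(p$pos - pos) < block_len + 2000L) {
              clash <- TRUE
              break
            }
          }
          if (!clash && !is.null(avoid)) {
            av <- avoid[avoid$chrom == cn, , drop = FALSE]
            if (nrow(av) > 0 &&
                any(pos + block_len + avoid_pad >= av$start &
                    pos - avoid_pad <= av$end)) {
              clash <- TRUE
            }
          }
          if (!clash) {
            placements[[length(placements) + 1L]] <-
              list(chrom = cn, pos = pos,
                   strand = sample(c("+", "-"), 1L))
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop(
            "build_reference: could not place fixed L1 copy ", i,
            " on ", cn, " without overlap after 1000 tries ",
            "(constraint: non-overlapping placements with ", margin,
            " bp end margin)"
          )
        }
      }
      # splice from rightmost to leftmost so earlier coordinates are stable
      ord <- order(
        vapply(placements, `[[`, character(1), "chrom"),
        -vapply(placements, `[[`, integer(1), "pos")
      )
      rows <- list()
      for (p in placements[ord]) {
        blk <- if (p$strand == "+") block_plus else revcomp(block_plus)
        s <- chroms[[p$chrom]]
        chroms[[p$chrom]] <- paste0(
          substr(s, 1L, p$pos), blk, substr(s, p$pos + 1L, nchar(s))
        )
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = p$chrom, start = p$pos + 1L, end = p$pos + block_len,
          strand = p$strand, id = NA_character_, stringsAsFactors = FALSE
        )
      }
      ann <- do.call(rbind, rows)
      # placements to the left shift annotations made earlier (to their right)
      ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
      for (cn in unique(ann$chrom)) {
        idx <- which(ann$chrom == cn)
        shift <- cumsum(c(0L, rep(block_len, length(idx) - 1L)))
        ann$start[idx] <- ann$start[idx] + shift
        ann$end[idx] <- ann$end[idx] + shift
      }
      ann$id <- sprintf("L1fixed_%02d", seq_len(nrow(ann)))
      rownames(ann) <- NULL
    }
    new_tip_genome(chroms, l1_annotation = ann)
  })
}

#' Mask annotated L1 intervals with N
#'
#' Replaces every annotated fixed-L1 interval by N, preserving length. Reads
#' originating inside fixed elements then fail to align, which is what makes
#' junction reads at both fixed and novel L1 3' ends recoverable as
#' "unmappable" reads.
#'
#' @param genome a `tip_genome`.
#' @param l1_annotation data.frame(chrom, start, end); defaults to the
#'   genome's own annotation.
#' @return a `tip_genome` with masked chromosomes.
#' @export
mask_reference <- function(genome, l1_annotation = genome$l1_annotation) {
  chroms <- genome$chromosomes
  if (nrow(l1_annotation) > 0) {
    for (i in seq_len(nrow(l1_annotation))) {
      cn <- l1_annotation$chrom[[i]]
      s <- l1_annotation$start[[i]]
      e <- l1_annotation$end[[i]]
      n <- nchar(chroms[[cn]])
      if (s < 1L || e > n || s > e) {
        stop("mask_reference: annotation interval out of bounds on ", cn)
      }
      substr(chroms[[cn]], s, e) <- strrep("N", e - s + 1L)
    }
  }
  out <- genome
  out$chromosomes <- chroms
  out
}
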