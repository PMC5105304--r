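# Vectorette-PCR read simulation.
#
# For every L1 3' end present on a haplotype (fixed reference copies and
# implanted insertions alike) and for each restriction enzyme, the simulator
# emits the amplicon running from the 3'UTR amplification anchor through the
# polyA tail and downstream flank to the first recognition site, shears it
# into ~300 bp fragments, and samples 75-100 bp reads (or read pairs from
# ~450 bp inserts) with substitution errors. Depth is therefore maximal
# immediately downstream of the junction, where all six enzyme amplicons
# overlap, and steps down as shorter amplicons run out -- the triangular
# pileup the assay is known for. Two kinds of noise are added: a fraction of
# uniformly drawn background reads, and a handful of "off-target
# amplification" loci that mimic vectorette mispriming (localized read
# stacks without L1 junction structure), which downstream stages use as
# presumed-negative training material.

#' Enumerate amplifiable L1 3' ends on a genome
#'
#' @param genome a `tip_genome` (one haplotype).
#' @return data.frame(id, kind, chrom, anchor_start, anchor_end, junction,
#'   direction): haplotype coordinates of the amplification anchor, the L1
#'   3' junction (last tail base adjacent to the flank), and the direction
#'   (+1 flank to the right, -1 flank to the left). Implants whose 3'
#'   element extent is too truncated to carry the anchor are omitted.
#' @export
l1_ends <- function(genome) {
  far <- L1_ANCHOR_FROM_3P[["far"]]
  near <- L1_ANCHOR_FROM_3P[["near"]]
  rows <- list()
  ann <- genome$l1_annotation
  if (nrow(ann) > 0) {
    for (i in seq_len(nrow(ann))) {
      if (ann$strand[i] == "+") {
        elem3 <- ann$end[i] - L1_FIXED_POLYA
        rows[[length(rows) + 1L]] <- data.frame(
          id = ann$id[i], kind = "fixed", chrom = ann$chrom[i],
          anchor_start = elem3 - far, anchor_end = elem3 - near,
          junction = ann$end[i], direction = 1L, stringsAsFactors = FALSE
        )
      } else {
        elem3 <- ann$start[i] + L1_FIXED_POLYA
        rows[[length(rows) + 1L]] <- data.frame(
          id = ann$id[i], kind = "fixed", chrom = ann$chrom[i],
          anchor_start = elem3 + near, anchor_end = elem3 + far,
          junction = ann$start[i], direction = -1L, stringsAsFactors = FALSE
        )
      }
    }
  }
  imp <- genome$implants
  if (nrow(imp) > 0) {
    for (i in seq_len(nrow(imp))) {
      e3 <- imp$element_length[i] - imp$inversion_length[i]
      if (e3 < l1_min_amplifiable()) next  # anchor truncated away
      if (imp$direction[i] == 1L) {
        elem3 <- imp$hap_junction[i] - imp$polyA_length[i]
        rows[[length(rows) + 1L]] <- data.frame(
          id = imp$id[i], kind = "implant", chrom = imp$chrom[i],
          anchor_start = elem3 - far, anchor_end = elem3 - near,
          junction = imp$hap_junction[i], direction = 1L,
          stringsAsFactors = FALSE
        )
      } else {
        elem3 <- imp$hap_junction[i] + imp$polyA_length[i]
        rows[[length(rows) + 1L]] <- data.frame(
          id = imp$id[i], kind = "implant", chrom = imp$chrom[i],
          anchor_start = elem3 + near, anchor_end = elem3 + far,
          junction = imp$hap_junction[i], direction = -1L,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(
      id = character(0), kind = character(0), chrom = character(0),
      anchor_start = integer(0), anchor_end = integer(0),
      junction = integer(0), direction = integer(0),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, rows)
}

# Amplicon for one L1 end and one enzyme, 5'->3' from the anchor. Returns
# list(seq, start, end, truncated) in haplotype plus-strand coordinates.
vectorette_amplicon <- function(hapseq, end_row, site, max_dist) {
  n <- nchar(hapseq)
  if (end_row$direction == 1L) {
    cut <- first_site(hapseq, site, from = end_row$junction + 30L,
                      direction = 1L, max_dist = max_dist)
    truncated <- is.na(cut)
    stop_at <- if (truncated) {
      min(n, end_row$junction + max_dist)
    } else {
      min(n, cut - 1L)
    }
    list(
      seq = substr(hapseq, end_row$anchor_start, stop_at),
      start = end_row$anchor_start, end = stop_at, truncated = truncated
    )
  } else {
    cut <- first_site(hapseq, site, from = end_row$junction - 30L,
                      direction = -1L, max_dist = max_dist)
    truncated <- is.na(cut)
    start_at <- if (truncated) {
      max(1L, end_row$junction - max_dist)
    } else {
      max(1L, cut + nchar(site))
    }
    list(
      seq = revcomp(substr(hapseq, start_at, end_row$anchor_end)),
      start = start_at, end = end_row$anchor_end, truncated = truncated
    )
  }
}

# Substitution errors at a fixed per-base rate.
add_substitutions <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  nmut <- stats::rbinom(length(seqs), lens, rate)
  for (i in which(nmut > 0L)) {
    pos <- sample.int(lens[i], nmut[i])
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
    }
    seqs[[i]] <- paste(ch, collapse = "")
  }
  seqs
}

# Sample shotgun reads from one template sequence. Single-end: shear into
# fragments (frag_mean +- frag_sd), read one end of each fragment on a
# random strand. Paired-end: size-selected inserts (insert_mean +-
# insert_sd), mates from both ends.
shear_and_read <- function(template, n_reads, layout,
                           read_len = c(75L, 100L),
                           frag_mean = 300, frag_sd = 60,
                           insert_mean = 450, insert_sd = 50) {
  tl <- nchar(template)
  if (n_reads <= 0L || tl < read_len[1L]) {
    return(data.frame(seq = character(0), mate_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  if (layout == "paired") {
    fl <- pmin(pmax(round(stats::rnorm(n_reads, insert_mean, insert_sd)),
                    2L * read_len[1L]), tl)
  } else {
    fl <- pmin(pmax(round(stats::rnorm(n_reads, frag_mean, frag_sd)),
                    read_len[1L]), tl)
  }
  start <- vapply(fl, function(l) sample.int(tl - l + 1L, 1L), integer(1))
  frag <- substring(template, start, start + fl - 1L)
  flip <- sample(c(TRUE, FALSE), n_reads, replace = TRUE)
  frag[flip] <- revcomp(frag[flip])
  rl1 <- pmin(sample(seq(read_len[1L], read_len[2L]), n_reads,
                     replace = TRUE), fl)
  if (layout == "paired") {
    rl2 <- pmin(sample(seq(read_len[1L], read_len[2L]), n_reads,
                       replace = TRUE), fl)
    data.frame(
      seq = substring(frag, 1L, rl1),
      mate_seq = revcomp(substring(frag, fl - rl2 + 1L, fl)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(seq = substring(frag, 1L, rl1),
               mate_seq = NA_character_, stringsAsFactors = FALSE)
  }
}

#' Simulate vectorette-PCR sequencing reads for one sample
#'
#' @param sample a `tip_sample` (diploid) or a single `tip_genome`
#'   (treated as one haplotype).
#' @param enzymes restriction enzyme table, see [vectorette_enzymes()].
#' @param coverage target read depth at an L1 junction present on every
#'   haplotype, aggregated over enzymes and haplotypes (a heterozygous
#'   junction receives about half).
#' @param error_rate per-base substitution probability.
#' @param seed integer seed; the run is fully reproducible.
#' @param layout "single" or "paired".
#' @param background_fraction fraction of total reads drawn uniformly from
#'   the genome.
#' @param offtarget_loci number of off-target (mispriming) amplicon loci
#'   per sample.
#' @param offtarget_depth depth range (min, max) for off-target loci.
#' @param read_len read length range (min, max) in bp.
#' @param max_dist maximum downstream distance searched for a restriction
#'   site; amplicons are truncated there when no site exists.
#' @return list with `reads` (data.frame: read_id, seq, qual, mate_seq,
#'   mate_qual), `layout`, `sample_id`, and `amplicons` (truth table with
#'   the source interval of every amplicon, its L1 end id, enzyme, and
#'   truncation flag).
#' @export
simulate_vectorette_reads <- function(sample,
                                      enzymes = vectorette_enzymes(),
                                      coverage = 30,
                                      error_rate = 0.002,
                                      seed = 1L,
                                      layout = c("single", "paired"),
                                      background_fraction = 0.05,
                                      offtarget_loci = 0L,
                                      offtarget_depth = c(4, 12),
                                      read_len = c(75L, 100L),
                                      max_dist = 2500L) {
  layout <- match.arg(layout)
  stopifnot(coverage > 0, nrow(enzymes) > 0)
  if (inherits(sample, "tip_genome")) {
    sample <- new_tip_sample("sample", list(h1 = sample))
  }
  haps <- sample$haplotypes
  n_hap <- length(haps)
  mean_rl <- mean(read_len)
  cov_unit <- coverage / n_hap / nrow(enzymes)

  withr::with_seed(seed, {
    read_rows <- list()
    amp_rows <- list()
    for (hi in seq_along(haps)) {
      hap <- haps[[hi]]
      ends <- l1_ends(hap)
      if (nrow(ends) > 0) {
        for (ei in seq_len(nrow(ends))) {
          er <- ends[ei, ]
          hapseq <- hap$chromosomes[[er$chrom]]
          for (zi in seq_len(nrow(enzymes))) {
            amp <- vectorette_amplicon(hapseq, er, enzymes$site[zi], max_dist)
            n_reads <- ceiling(nchar(amp$seq) * cov_unit / mean_rl)
            rd <- shear_and_read(amp$seq, n_reads, layout,
                                 read_len = read_len)
            read_rows[[length(read_rows) + 1L]] <- rd
            amp_rows[[length(amp_rows) + 1L]] <- data.frame(
              l1_end = er$id, kind = er$kind, enzyme = enzymes$name[zi],
              haplotype = names(haps)[hi] %||% as.character(hi),
              chrom = er$chrom, start = amp$start, end = amp$end,
              length = nchar(amp$seq), truncated = amp$truncated,
              n_reads = nrow(rd), stringsAsFactors = FALSE
            )
          }
        }
      }
      # off-target mispriming amplicons
      if (offtarget_loci > 0L) {
        n_per_hap <- offtarget_loci %/% n_hap +
          (hi <= offtarget_loci %% n_hap)
        clens <- nchar(hap$chromosomes)
        for (oi in seq_len(n_per_hap)) {
          cn <- sample(names(clens), 1L, prob = clens / sum(clens))
          alen <- sample(800:2000, 1L)
          pos <- sample.int(max(1L, clens[[cn]] - alen), 1L)
          aseq <- substr(hap$chromosomes[[cn]], pos, pos + alen - 1L)
          depth <- stats::runif(1L, offtarget_depth[1L], offtarget_depth[2L])
          n_reads <- ceiling(alen * depth / mean_rl)
          rd <- shear_and_read(aseq, n_reads, layout, read_len = read_len)
          read_rows[[length(read_rows) + 1L]] <- rd
          amp_rows[[length(amp_rows) + 1L]] <- data.frame(
            l1_end = NA_character_, kind = "offtarget",
            enzyme = NA_character_,
            haplotype = names(haps)[hi] %||% as.character(hi),
            chrom = cn, start = pos, end = pos + alen - 1L,
            length = alen, truncated = FALSE, n_reads = nrow(rd),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    reads <- if (length(read_rows)) {
      do.call(rbind, read_rows)
    } else {
      data.frame(seq = character(0), mate_seq = character(0),
                 stringsAsFactors = FALSE)
    }

    # uniform background
    n_signal <- nrow(reads)
    n_bg <- round(background_fraction / (1 - background_fraction) *
                    n_signal)
    if (background_fraction > 0 && n_signal == 0) n_bg <- 0L
    if (n_bg > 0L) {
      bg <- list()
      hap_idx <- sample.int(n_hap, n_bg, replace = TRUE)
      for (i in seq_len(n_bg)) {
        hap <- haps[[hap_idx[i]]]
        clens <- nchar(hap$chromosomes)
        cn <- sample(names(clens), 1L, prob = clens / sum(clens))
        rl <- sample(seq(read_len[1L], read_len[2L]), 1L)
        if (layout == "paired") {
          fl <- min(max(round(stats::rnorm(1L, 450, 50)), 2L * rl),
                    clens[[cn]] - 1L)
          pos <- sample.int(clens[[cn]] - fl, 1L)
          frag <- substr(hap$chromosomes[[cn]], pos, pos + fl - 1L)
          if (sample(c(TRUE, FALSE), 1L)) frag <- revcomp(frag)
          bg[[i]] <- data.frame(
            seq = substr(frag, 1L, rl),
            mate_seq = revcomp(substr(frag, fl - rl + 1L, fl)),
            stringsAsFactors = FALSE
          )
        } else {
          pos <- sample.int(clens[[cn]] - rl, 1L)
          s <- substr(hap$chromosomes[[cn]], pos, pos + rl - 1L)
          if (sample(c(TRUE, FALSE), 1L)) s <- revcomp(s)
          bg[[i]] <- data.frame(seq = s, mate_seq = NA_character_,
                                stringsAsFactors = FALSE)
        }
      }
      reads <- rbind(reads, do.call(rbind, bg))
    }

    if (nrow(reads) > 0) {
      reads$seq <- add_substitutions(reads$seq, error_rate)
      paired <- !is.na(reads$mate_seq)
      reads$mate_seq[paired] <- add_substitutions(reads$mate_seq[paired],
                                                  error_rate)
      reads$read_id <- sprintf("%s_r%06d", sample$sample_id,
                               seq_len(nrow(reads)))
      reads$qual <- strrep("I", nchar(reads$seq))
      reads$mate_qual <- ifelse(paired, strrep("I", nchar(reads$mate_seq)),
                                NA_character_)
      reads <- reads[, c("read_id", "seq", "qual", "mate_seq", "mate_qual")]
    } else {
      reads <- data.frame(
        read_id = character(0), seq = character(0), qual = character(0),
        mate_seq = character(0), mate_qual = character(0),
        stringsAsFactors = FALSE
      )
    }

    list(
      reads = reads,
      layout = layout,
      sample_id = sample$sample_id,
      amplicons = if (length(amp_rows)) do.call(rbind, amp_rows) else NULL
    )
  })
}
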