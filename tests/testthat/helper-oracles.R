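# Independent oracles used by the oracle-equivalence tests. These are
# deliberately naive (exhaustive scans, quadratic DP) and share no code
# with the implementation paths they check.

# exhaustive ungapped alignment over every position and both strands
oracle_align_one <- function(seq, chroms, max_mismatch_rate = 0.03,
                             unique_margin = 2L) {
  len <- nchar(seq)
  max_mm <- floor(len * max_mismatch_rate)
  hits <- list()
  for (cn in names(chroms)) {
    ref <- strsplit(chroms[[cn]], "", fixed = TRUE)[[1]]
    L <- length(ref)
    if (L < len) next
    n_pos <- L - len + 1L
    for (strand in c("+", "-")) {
      q <- if (strand == "+") seq else tipseqr:::revcomp(seq)
      qv <- strsplit(q, "", fixed = TRUE)[[1]]
      mm <- integer(n_pos)
      for (j in seq_len(len)) {
        mm <- mm + (ref[j:(j + n_pos - 1L)] != qv[j])
      }
      ok <- which(mm <= max_mm)
      if (length(ok)) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = cn, start = ok, strand = strand, mm = mm[ok],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(hits) == 0L) return(list(status = "unmapped"))
  h <- do.call(rbind, hits)
  h <- h[order(h$mm, h$chrom, h$start, h$strand), , drop = FALSE]
  best <- h[1L, ]
  n_best <- sum(h$mm == best$mm)
  runner <- if (nrow(h) > 1L) h$mm[2L] else Inf
  status <- if (n_best > 1L || (runner - best$mm) < unique_margin) {
    "multi"
  } else {
    "unique"
  }
  list(status = status, chrom = best$chrom, start = best$start,
       strand = best$strand, mismatches = best$mm)
}

# per-base depth histogram from alignment intervals (one chromosome)
oracle_pileup <- function(starts, ends, L) {
  depth <- integer(L)
  for (i in seq_along(starts)) {
    depth[starts[i]:ends[i]] <- depth[starts[i]:ends[i]] + 1L
  }
  depth
}

# quadratic Gotoh local alignment score, same scoring as align_to_l1
# (match 1, mismatch -1, gap of length k costs 4 + k)
oracle_local_score <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1L, m + 1L)
  Ix <- matrix(-Inf, n + 1L, m + 1L)
  Iy <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- if (av[i - 1L] == bv[j - 1L]) 1 else -1
      M[i, j] <- max(0, M[i - 1L, j - 1L] + s, Ix[i - 1L, j - 1L] + s,
                     Iy[i - 1L, j - 1L] + s)
      Ix[i, j] <- max(M[i - 1L, j] - 5, Ix[i - 1L, j] - 1)
      Iy[i, j] <- max(M[i, j - 1L] - 5, Iy[i, j - 1L] - 1)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# brute-force gene-context scan
oracle_gene_context <- function(chrom, pos, genes, exons) {
  hit <- NULL
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] == chrom && genes$start[i] <= pos &&
        genes$end[i] >= pos) {
      hit <- genes$gene[i]
      break
    }
  }
  if (is.null(hit)) return("intergenic")
  for (i in seq_len(nrow(exons))) {
    if (exons$gene[i] == hit && exons$start[i] <= pos &&
        exons$end[i] >= pos) {
      return("exon")
    }
  }
  "intron"
}

# small deterministic reference + implant fixture shared across tests
make_toy_world <- function(seed = 1L, n_fixed = 6L,
                           chrom_lengths = c(chrA = 100000L,
                                             chrB = 100000L)) {
  ref <- build_reference(
    seed, chrom_lengths, n_fixed,
    avoid = data.frame(chrom = "chrA", start = 40000L, end = 60000L,
                       stringsAsFactors = FALSE)
  )
  ins <- truth_insertion("chrA", 50010, 50001, "+", 1839, 662,
                         polyA_length = 30, id = "toy1")
  segs <- data.frame(chrom = "chrA", start = 40000L, end = 60000L,
                     copy_number = 1L, loh = TRUE,
                     stringsAsFactors = FALSE)
  pair <- build_patient_pair(ref, "P1", insertions = ins, segments = segs)
  list(reference = ref, insertion = ins, pair = pair, segments = segs)
}

# random TruthInsertion specs for property tests (well inside chrom bounds)
random_insertion_specs <- function(n, chrom = "chrA", lo = 20000L,
                                   hi = 80000L) {
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    elen <- sample(700:6059, 1L)
    inv <- if (stats::runif(1) < 0.4) {
      sample.int(min(1000L, elen - 400L), 1L)
    } else {
      0L
    }
    tsd <- sample(5:20, 1L)
    j3 <- sample(lo:hi, 1L)
    j5 <- j3 + sample(c(-1L, 1L), 1L) * (tsd - 1L)
    specs[[i]] <- truth_insertion(
      chrom, j5, j3, sample(c("+", "-"), 1L), elen, inv,
      polyA_length = sample(10:40, 1L), id = sprintf("rand%03d", i)
    )
  }
  do.call(rbind, specs)
}
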