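# Generator: reference construction, implant arithmetic, CN/LOH handling,
# and vectorette read simulation.

test_that("build_reference is deterministic and places anchored L1 copies", {
  g0 <- build_reference(1, c(chr1 = 200000L), n_fixed_l1 = 0L)
  expect_equal(nrow(g0$l1_annotation), 0L)
  expect_equal(nchar(g0$chromosomes[["chr1"]]), 200000L)

  g1 <- build_reference(1, c(chr1 = 200000L), n_fixed_l1 = 5L)
  g2 <- build_reference(1, c(chr1 = 200000L), n_fixed_l1 = 5L)
  expect_identical(g1$chromosomes, g2$chromosomes)
  expect_identical(g1$l1_annotation, g2$l1_annotation)

  # oracle: every annotated interval contains the 3'UTR anchor subsequence,
  # and a direct scan of the genome finds exactly those occurrences
  anchor <- tipseqr:::l1_anchor_seq()
  chrseq <- Biostrings::DNAString(g1$chromosomes[["chr1"]])
  fwd <- BiocGenerics::start(Biostrings::matchPattern(anchor, chrseq))
  rev <- BiocGenerics::start(Biostrings::matchPattern(
    tipseqr:::revcomp(anchor), chrseq))
  expect_equal(length(fwd) + length(rev), 5L)
  for (i in seq_len(5L)) {
    ann <- g1$l1_annotation[i, ]
    inside <- c(fwd, rev)
    expect_true(any(inside >= ann$start & inside <= ann$end))
    sub <- substr(g1$chromosomes[["chr1"]], ann$start, ann$end)
    hit <- if (ann$strand == "+") {
      grepl(anchor, sub, fixed = TRUE)
    } else {
      grepl(tipseqr:::revcomp(anchor), sub, fixed = TRUE)
    }
    expect_true(hit)
  }
})

test_that("implant_insertion builds the TPRT allele structure", {
  ref <- build_reference(3, c(chrA = 60000L), n_fixed_l1 = 0L)
  l1 <- l1_consensus()

  # the published somatic configuration: 1839 bp element with a 662 bp 5'
  # inversion and a 10 bp TSD
  ins <- truth_insertion("chrA", 30010, 30001, "+", 1839, 662,
                         polyA_length = 30, id = "s1")
  g <- implant_insertion(ref, ins)
  expect_equal(nchar(g$chromosomes[["chrA"]]) - 60000L, ins$ins_size)

  body_start <- ins$tsd_end + 1L
  body <- substr(g$chromosomes[["chrA"]], body_start,
                 body_start + 1839L + 30L - 1L)
  tsd_seq <- substr(ref$chromosomes[["chrA"]], ins$tsd_start, ins$tsd_end)
  # allele = TSD . body . TSD: both duplicated copies flank the body
  expect_equal(substr(g$chromosomes[["chrA"]], ins$tsd_start, ins$tsd_end),
               tsd_seq)
  expect_equal(substr(g$chromosomes[["chrA"]], body_start + 1869L,
                      body_start + 1869L + 9L), tsd_seq)
  # 5' inverted portion reverse-complements onto the consensus
  inv_part <- substr(body, 1L, 662L)
  e3 <- 1839L - 662L
  expect_equal(
    tipseqr:::revcomp(inv_part),
    substr(l1$sequence, 6059L - e3 - 662L + 1L, 6059L - e3)
  )
  # 3' portion matches the consensus terminus, then the polyA
  expect_equal(substr(body, 663L, 1839L),
               substring(l1$sequence, 6059L - e3 + 1L))
  expect_equal(substr(body, 1840L, 1869L), strrep("A", 30L))

  # identity case: full-length uninverted insertion carries the whole
  # consensus verbatim
  ins2 <- truth_insertion("chrA", 45001, 45008, "+", 6059, 0,
                          polyA_length = 20, id = "s2")
  g2 <- implant_insertion(ref, ins2)
  expect_true(grepl(l1$sequence, g2$chromosomes[["chrA"]], fixed = TRUE))

  # invariant violations are named
  expect_error(truth_insertion("chrA", 100, 91, "+", 500, 0,
                               tsd_length = 5), "tsd_length")
  expect_error(truth_insertion("chrA", 100, 91, "+", 500, 500),
               "inversion_length")
  expect_error(truth_insertion("chrA", 100, 91, "+", 9000, 0),
               "consensus length")
})

test_that("round trip: characterize_insertion recovers implant parameters", {
  ref <- build_reference(4, c(chrA = 50000L), n_fixed_l1 = 0L)
  ins <- truth_insertion("chrA", 25010, 25001, "+", 1839, 662,
                         polyA_length = 30, id = "rt")
  loc <- insertion_locus(ref, ins)
  ch <- characterize_insertion(loc$allele, loc$flank5, loc$flank3)
  expect_equal(ch$strand, "+")
  expect_equal(ch$element_length, 1839L)
  expect_equal(ch$inversion_length, 662L)
  expect_equal(ch$polyA_length, 30L)
  expect_equal(ch$tsd_length, 10L)
})

test_that("implanted length changes are conserved in the blood genome", {
  ref <- build_reference(5, c(chrA = 90000L), n_fixed_l1 = 0L)
  withr::with_seed(42, {
    specs <- random_insertion_specs(6, lo = 10000L, hi = 80000L)
  })
  # keep target sites pairwise clear
  specs <- specs[order(specs$tsd_start), ]
  specs <- specs[c(TRUE, diff(specs$tsd_start) > 500L), , drop = FALSE]
  pair <- build_patient_pair(ref, "P", insertions = specs)
  diff_len <- nchar(pair$blood$haplotypes$h1$chromosomes[["chrA"]]) -
    nchar(ref$chromosomes[["chrA"]])
  expect_equal(diff_len, sum(specs$ins_size))
  # no CN events: tumor and blood haplotype 1 are identical (no somatic)
  expect_identical(pair$blood$haplotypes$h1$chromosomes,
                   pair$tumor$haplotypes$h1$chromosomes)
})

test_that("table2 presets reproduce the printed panel", {
  p <- table2_presets()
  expect_equal(sum(!p$somatic), 11L)  # blood-specific insertions
  expect_equal(sum(p$somatic), 1L)
  expect_equal(sum(p$partial), 3L)

  r750 <- p[p$sample_id == "750" & p$chrom == "chr13", ]
  expect_equal(r750$element_length, 4162L)
  expect_equal(r750$tsd_length, 17L)
  expect_equal(r750$strand, "+")

  r083 <- p[p$sample_id == "083", ]
  expect_true(r083$somatic)
  expect_equal(r083$element_length, 1839L)
  expect_equal(r083$inversion_length, 662L)
  expect_equal(r083$tsd_length, 10L)

  # TSD consistency across the panel, including the printed coordinates
  expect_equal(p$tsd_length, measure_tsd(p$junction5, p$junction3))
  full <- p[!p$partial, ]
  expect_equal(measure_tsd(full$printed_junction5, full$printed_junction3),
               full$printed_tsd_length)
})

test_that("apply_cn_loh removes the carrier allele from the tumor", {
  ref <- build_reference(6, c(chrA = 100000L, chrB = 100000L),
                         n_fixed_l1 = 2L,
                         avoid = data.frame(chrom = c("chrA", "chrA"),
                                            start = c(30000L, 70000L),
                                            end = c(30100L, 70100L)))
  ins <- rbind(
    truth_insertion("chrA", 30001, 30010, "+", 2000, 0, id = "i1"),
    truth_insertion("chrA", 70001, 70008, "-", 1500, 0, id = "i2")
  )

  # empty segment list: tumor == blood (no somatic implants)
  pair0 <- build_patient_pair(ref, "P", insertions = ins)
  expect_identical(pair0$blood$haplotypes$h1$chromosomes,
                   pair0$tumor$haplotypes$h1$chromosomes)

  # copy-neutral LOH over the first implant only
  segs <- data.frame(chrom = "chrA", start = 25000L, end = 35000L,
                     copy_number = 2L, loh = TRUE)
  pair <- apply_cn_loh(pair0, segs)
  expect_equal(pair$truth$blood_only_loss, c(TRUE, FALSE))
  expect_equal(pair$truth$cn[1], 2L)
  tumor_ids <- l1_ends(pair$tumor$haplotypes$h1)$id
  blood_ids <- l1_ends(pair$blood$haplotypes$h1)$id
  expect_true("i1" %in% blood_ids && !"i1" %in% tumor_ids)
  expect_true("i2" %in% tumor_ids)

  # whole-chromosome copy-neutral LOH: every heterozygous implant on it
  # becomes blood-only
  segs2 <- data.frame(chrom = "chrA", start = 1L, end = 100000L,
                      copy_number = 2L, loh = TRUE)
  pair2 <- apply_cn_loh(pair0, segs2)
  expect_true(all(pair2$truth$blood_only_loss))
  expect_false(any(c("i1", "i2") %in%
                     l1_ends(pair2$tumor$haplotypes$h1)$id))

  # a CN 1 deletion removes the carrier haplotype segment outright: the
  # tumor loses both the implant (LOH resolution) and the segment bases
  segs3 <- data.frame(chrom = "chrA", start = 25000L, end = 35000L,
                      copy_number = 1L, loh = TRUE)
  pair3 <- apply_cn_loh(pair0, segs3)
  expect_equal(nchar(pair3$tumor$haplotypes$h1$chromosomes[["chrA"]]),
               nchar(pair0$tumor$haplotypes$h1$chromosomes[["chrA"]]) -
                 (35000L - 25000L + 1L) - ins$ins_size[1])

  # invariant: CN 1 implies LOH
  expect_error(
    apply_cn_loh(pair0, data.frame(chrom = "chrA", start = 1, end = 10,
                                   copy_number = 1L, loh = FALSE)),
    "implies"
  )
})

test_that("vectorette simulation emits amplicon-shaped reads", {
  # no L1 ends, no background: empty read set
  bare <- tipseqr:::new_tip_genome(
    c(chrZ = paste(rep("ACGT", 2000), collapse = ""))
  )
  rs0 <- simulate_vectorette_reads(bare, coverage = 10, seed = 1,
                                   background_fraction = 0)
  expect_equal(nrow(rs0$reads), 0L)

  # determinism
  ref <- build_reference(7, c(chrA = 60000L), n_fixed_l1 = 1L)
  a <- simulate_vectorette_reads(ref, coverage = 10, seed = 5,
                                 offtarget_loci = 2L)
  b <- simulate_vectorette_reads(ref, coverage = 10, seed = 5,
                                 offtarget_loci = 2L)
  expect_identical(a$reads, b$reads)
  expect_identical(a$amplicons, b$amplicons)

  # at error rate 0 with one enzyme, every signal read is an exact
  # substring of its truth amplicon (forward or reverse complement)
  enz1 <- vectorette_enzymes()[1, , drop = FALSE]
  rs <- simulate_vectorette_reads(ref, enzymes = enz1, coverage = 15,
                                  error_rate = 0, seed = 9,
                                  background_fraction = 0)
  expect_gt(nrow(rs$reads), 10L)
  amp <- rs$amplicons
  hap <- ref$chromosomes[[amp$chrom[1]]]
  amp_seq <- substr(hap, amp$start[1], amp$end[1])
  if (l1_ends(ref)$direction[1] == -1L) {
    amp_seq <- tipseqr:::revcomp(amp_seq)
  }
  ok <- vapply(rs$reads$seq, function(s) {
    grepl(s, amp_seq, fixed = TRUE) ||
      grepl(tipseqr:::revcomp(s), amp_seq, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))

  # read lengths inside the configured envelope, qualities match
  expect_true(all(nchar(rs$reads$seq) >= 75L & nchar(rs$reads$seq) <= 100L))
  expect_equal(nchar(rs$reads$seq), nchar(rs$reads$qual))
})

test_that("junction pileup decays downstream of the junction", {
  ref <- build_reference(8, c(chrA = 60000L), n_fixed_l1 = 0L)
  ins <- truth_insertion("chrA", 30001, 30010, "+", 4000, 0,
                         polyA_length = 25, id = "d1")
  g <- implant_insertion(ref, ins)
  rs <- simulate_vectorette_reads(g, coverage = 40, error_rate = 0,
                                  seed = 3, background_fraction = 0)
  aln <- align_reads(
    data.frame(read_id = rs$reads$read_id, seq = rs$reads$seq),
    mask_reference(ref)
  )
  aln <- aln[aln$status == "unique" & !is.na(aln$chrom), ]
  depth <- oracle_pileup(aln$start, aln$end, 60000L)
  j <- ins$tsd_end  # flank side starts here in reference coordinates
  win <- function(a, b) mean(depth[(j + a):(j + b)])
  # depth within the fragment-length plateau, then 1 kb downstream, then
  # 2 kb downstream: non-increasing (union of nested enzyme amplicons)
  expect_gte(win(50, 400) + 1e-9, win(1000, 1400))
  expect_gte(win(1000, 1400) + 1e-9, win(2000, 2400))
})
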