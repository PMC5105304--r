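# Candidate selection, the five-feature vectors, and the within-sample
# ridge logistic scorer.

mk_peaks <- function(n, chrom = "chr1", start = seq(1000L, by = 20000L,
                                                    length.out = n),
                     width = 2000L, depth = 30L) {
  data.frame(
    peak_id = sprintf("%s:%d", chrom, start), chrom = chrom,
    start = start, end = start + width - 1L,
    read_count = depth, max_coverage = depth, rank = seq_len(n),
    stringsAsFactors = FALSE
  )
}

mk_jr <- function(peak_id, n_each, overhang = paste0(strrep("A", 20),
                                                     "GCGC")) {
  do.call(rbind, lapply(seq_along(peak_id), function(i) {
    if (n_each[i] == 0L) return(NULL)
    data.frame(
      peak_id = peak_id[i],
      read_id = sprintf("%s_j%03d", peak_id[i], seq_len(n_each[i])),
      anchored_end = "three_prime", chrom = "chr1",
      anchor_start = 1000L, anchor_end = 1034L, anchor_strand = "+",
      anchor_mismatches = 0L, side = "left", overhang = overhang,
      gseq = overhang, polyAT_run = tipseqr:::longest_at_run(overhang),
      stringsAsFactors = FALSE
    )
  }))
}

test_that("candidates are exactly the peaks with junction evidence", {
  pk <- mk_peaks(5)
  jr <- mk_jr(pk$peak_id[c(1, 3, 4)], c(3L, 1L, 7L))
  cand <- select_candidates(pk, jr)
  expect_setequal(cand$peak_id, pk$peak_id[c(1, 3, 4)])
  expect_equal(cand$junction_count[match(pk$peak_id[3], cand$peak_id)], 1L)

  # counting oracle: brute-force tally over the junction map
  oracle <- table(jr$peak_id)
  for (i in seq_len(nrow(cand))) {
    expect_equal(cand$junction_count[i],
                 as.integer(oracle[[cand$peak_id[i]]]))
  }
  # paired layout counts read pairs once
  jr2 <- mk_jr(pk$peak_id[1], 1L)
  jr2 <- rbind(jr2, jr2)
  jr2$read_id <- c("frag1/1", "frag1/2")
  expect_equal(select_candidates(pk, jr2, layout = "paired")$junction_count,
               1L)
})

test_that("feature vectors match direct recounts", {
  pk <- mk_peaks(1, start = 1000L, width = 100L, depth = 10L)
  aln <- data.frame(
    read_id = sprintf("r%02d", 1:10), chrom = "chr1",
    start = 1000L, end = 1099L, strand = "+", mismatches = 0L,
    status = "unique", stringsAsFactors = FALSE
  )
  f <- compute_features(pk, aln, mk_jr(pk$peak_id, 2L))
  expect_equal(f$peak_width, 100L)
  expect_equal(f$peak_depth, 10L)
  expect_equal(f$variant_index, 0)
  expect_equal(f$junction_read_count, 2L)
  # overhangs of pure A: tail purity 1
  expect_equal(f$polyA_purity, 1)
  expect_equal(tipseqr:::polyA_tail_purity(strrep("A", 20)), 1)

  # variant index equals a per-read recount at ~2 substitutions / 100 bp
  aln$mismatches <- rep(2L, 10)
  f2 <- compute_features(pk, aln, mk_jr(pk$peak_id, 2L))
  expect_equal(f2$variant_index, mean(2 / 100))

  # a peak without any aligned read is a contradiction
  pk_bad <- mk_peaks(1, start = 90000L)
  expect_error(compute_features(pk_bad, aln, mk_jr(pk_bad$peak_id, 1L)),
               "no aligned reads")
})

# separable synthetic features: positives near annotated 3' ends with
# strong junction evidence, negatives far away with none
make_training_world <- function(n_pos = 6L, n_neg = 10L, seed = 61) {
  ann <- data.frame(
    chrom = "chr1",
    start = seq(5000L, by = 50000L, length.out = n_pos),
    end = seq(5000L, by = 50000L, length.out = n_pos) + 6078L,
    strand = "+", id = sprintf("L1f%02d", seq_len(n_pos)),
    stringsAsFactors = FALSE
  )
  pos <- mk_peaks(n_pos, start = ann$end + 1L)
  neg <- mk_peaks(n_neg, start = seq(30000L, by = 50000L,
                                     length.out = n_neg), depth = 8L)
  withr::with_seed(seed, {
    pos$peak_width <- pos$end - pos$start + 1L
    pos$peak_depth <- pos$max_coverage + rpois(n_pos, 4)
    pos$variant_index <- runif(n_pos, 0, 0.01)
    pos$polyA_purity <- runif(n_pos, 0.9, 1)
    pos$junction_read_count <- sample(8:20, n_pos, replace = TRUE)
    pos$junction_count <- pos$junction_read_count
    neg$peak_width <- neg$end - neg$start + 1L
    neg$peak_depth <- neg$max_coverage
    neg$variant_index <- runif(n_neg, 0, 0.02)
    neg$polyA_purity <- runif(n_neg, 0.2, 0.4)
    neg$junction_read_count <- 0L
    neg$junction_count <- 0L
  })
  list(features = rbind(pos, neg), annotation = ann, n_pos = n_pos)
}

test_that("training separates constructed positives from negatives", {
  w <- make_training_world()
  sc <- train_model(w$features, w$annotation, seed = 3)
  expect_length(sc$positives, w$n_pos)
  scored <- score_candidates(sc, w$features)
  expect_true(all(scored$probability >= 0 & scored$probability <= 1))
  # training accuracy 1 on separable features
  lab <- w$features$peak_id %in% sc$positives
  expect_true(all(scored$probability[lab] > 0.5))
  neg_lab <- w$features$peak_id %in% sc$negatives
  expect_true(all(scored$probability[neg_lab] < 0.5))
  # every known positive outscores the median presumed negative
  expect_true(min(scored$probability[lab]) >=
                stats::median(scored$probability[neg_lab]))

  # deterministic refit
  sc2 <- train_model(w$features, w$annotation, seed = 3)
  expect_identical(sc$coefficients, sc2$coefficients)

  # insufficient labels are refused with the minimum counts stated
  expect_error(train_model(w$features[1:6, ], w$annotation),
               "at least 5")
})

test_that("uninformative features score near chance on held-out peaks", {
  w <- make_training_world(n_pos = 8L, n_neg = 40L)
  withr::with_seed(99, {
    # destroy the signal: all five features drawn iid regardless of label
    for (col in tipseqr:::FEATURE_NAMES) {
      w$features[[col]] <- stats::rnorm(nrow(w$features))
    }
    w$features$junction_count <- 1L  # keep candidacy labels intact
    holdout <- mk_peaks(200L, start = seq(1001L, by = 997L,
                                          length.out = 200L))
    for (col in tipseqr:::FEATURE_NAMES) {
      holdout[[col]] <- stats::rnorm(200)
    }
    truth_lab <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  })
  sc <- train_model(w$features, w$annotation, seed = 11)
  p <- score_candidates(sc, holdout)$probability
  acc <- mean((p > 0.5) == truth_lab)
  expect_lt(abs(acc - 0.5), 0.12)
})

test_that("probability is monotone in a positively weighted feature", {
  w <- make_training_world()
  sc <- train_model(w$features, w$annotation, seed = 3)
  beta_jr <- sc$coefficients[["junction_read_count"]]
  expect_gt(beta_jr, 0)
  base <- w$features[1, ]
  hi <- base
  hi$junction_read_count <- base$junction_read_count + 10L
  p <- score_candidates(sc, rbind(base, hi))$probability
  expect_gte(p[2], p[1])

  # empty candidate list passes through
  empty <- w$features[0, ]
  expect_equal(nrow(score_candidates(sc, empty)), 0L)
})
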