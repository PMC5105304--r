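# Approach 2: candidate sites are peaks with junction evidence; each gets a
# five-feature vector (peak width, peak depth, variant index, polyA tail
# purity, junction read count) and a probability from a ridge-regularized
# logistic model trained within-sample on peaks at known (annotated) L1 3'
# ends versus presumed negatives far from any known element.

#' Select candidate insertion sites
#'
#' Exactly the peaks with at least one junction read (single-end layout) or
#' at least one junction-containing read pair (paired layout, where mates
#' share a read id base) become candidates.
#'
#' @param peaks peak table from [call_peaks()].
#' @param junction_reads table from [extract_junction_reads()].
#' @param layout "single" or "paired".
#' @return subset of `peaks` with a `junction_count` column.
#' @export
select_candidates <- function(peaks, junction_reads,
                              layout = c("single", "paired")) {
  layout <- match.arg(layout)
  if (nrow(peaks) == 0L) {
    peaks$junction_count <- integer(0)
    return(peaks)
  }
  unit <- junction_reads$read_id
  if (layout == "paired") unit <- sub("/[12]$", "", unit)
  cnt <- tapply(unit, junction_reads$peak_id,
                function(x) length(unique(x)))
  peaks$junction_count <- as.integer(cnt[peaks$peak_id])
  peaks$junction_count[is.na(peaks$junction_count)] <- 0L
  peaks[peaks$junction_count >= 1L, , drop = FALSE]
}

FEATURE_NAMES <- c("peak_width", "peak_depth", "variant_index",
                   "polyA_purity", "junction_read_count")

#' Compute the five-feature vector per peak
#'
#' Width = end - start + 1; depth = maximum per-base coverage; variant
#' index = mean per-read mismatch fraction over uniquely aligned reads in
#' the peak interval; polyA purity = mean tail purity over the peak's
#' junction-read overhangs (0 when there are none); junction read count.
#'
#' @param peaks peak table (candidates or all peaks).
#' @param alignments alignment table from [align_reads()].
#' @param junction_reads junction-read table.
#' @param layout read layout, for pair-aware junction counting.
#' @return `peaks` with the five feature columns appended.
#' @export
compute_features <- function(peaks, alignments, junction_reads,
                             layout = c("single", "paired")) {
  layout <- match.arg(layout)
  n <- nrow(peaks)
  peaks$peak_width <- peaks$end - peaks$start + 1L
  peaks$peak_depth <- peaks$max_coverage
  peaks$variant_index <- rep(NA_real_, n)
  peaks$polyA_purity <- rep(0, n)
  peaks$junction_read_count <- rep(0L, n)
  if (n == 0L) return(peaks)
  aln <- alignments[alignments$status == "unique", , drop = FALSE]
  for (i in seq_len(n)) {
    sel <- aln$chrom == peaks$chrom[i] & aln$start <= peaks$end[i] &
      aln$end >= peaks$start[i]
    if (!any(sel)) {
      stop("compute_features: peak ", peaks$peak_id[i],
           " contains no aligned reads")
    }
    peaks$variant_index[i] <-
      mean(aln$mismatches[sel] / (aln$end[sel] - aln$start[sel] + 1L))
    jr <- junction_reads[junction_reads$peak_id == peaks$peak_id[i], ,
                         drop = FALSE]
    if (nrow(jr) > 0L) {
      peaks$polyA_purity[i] <-
        mean(vapply(jr$overhang, polyA_tail_purity, numeric(1)))
      unit <- jr$read_id
      if (layout == "paired") unit <- sub("/[12]$", "", unit)
      peaks$junction_read_count[i] <- length(unique(unit))
    }
  }
  peaks
}

# 3' junction coordinate of an annotated L1 copy (tail side)
annotation_3prime <- function(l1_annotation) {
  ifelse(l1_annotation$strand == "+", l1_annotation$end,
         l1_annotation$start)
}

#' Train the within-sample candidate scorer
#'
#' Candidates whose peak lies within `positive_window` bp of an annotated
#' L1 3' end are labeled known positives; presumed negatives are sampled
#' from peaks farther than `far_dist` from any annotated element. A
#' ridge-regularized logistic model on the standardized five features is
#' fitted (deterministically, given the seed used for negative sampling).
#'
#' @param features peak table with feature columns from
#'   [compute_features()] covering *all* peaks (candidates and not); the
#'   `junction_count` column marks candidacy where present.
#' @param known_l1_annotation fixed-L1 annotation data.frame.
#' @param negatives_per_positive negatives sampled per positive.
#' @param seed RNG seed for negative sampling.
#' @param positive_window distance from an annotated 3' end for a positive.
#' @param far_dist minimum distance from any annotated element for a
#'   presumed negative.
#' @param lambda ridge penalty.
#' @return a `tip_scorer`: list(fit, center, scale, lambda, coefficients,
#'   positives, negatives).
#' @export
train_model <- function(features, known_l1_annotation,
                        negatives_per_positive = 1L, seed = 1L,
                        positive_window = 500L, far_dist = 10000L,
                        lambda = 0.01) {
  stopifnot(all(FEATURE_NAMES %in% names(features)))
  ann <- known_l1_annotation
  p3 <- annotation_3prime(ann)
  dist_to_pos3 <- function(i) {
    sel <- ann$chrom == features$chrom[i]
    if (!any(sel)) return(Inf)
    min(pmax(0L, pmax(p3[sel] - features$end[i],
                      features$start[i] - p3[sel])))
  }
  dist_to_ann <- function(i) {
    sel <- ann$chrom == features$chrom[i]
    if (!any(sel)) return(Inf)
    min(pmax(0L, pmax(ann$start[sel] - features$end[i],
                      features$start[i] - ann$end[sel])))
  }
  n <- nrow(features)
  d3 <- vapply(seq_len(n), dist_to_pos3, numeric(1))
  da <- vapply(seq_len(n), dist_to_ann, numeric(1))
  is_candidate <- if ("junction_count" %in% names(features)) {
    features$junction_count >= 1L
  } else {
    features$junction_read_count >= 1L
  }
  pos_idx <- which(d3 <= positive_window & is_candidate)
  far <- which(da > far_dist & !(seq_len(n) %in% pos_idx))
  # presumed negatives: prefer far peaks with no junction evidence, so a
  # genuine novel insertion among the far peaks does not poison its own
  # training label; fall back to all far peaks when too few exist
  neg_pool <- far[!is_candidate[far]]
  if (length(neg_pool) < 5L) neg_pool <- far
  if (length(pos_idx) < 5L || length(neg_pool) < 5L) {
    stop(
      "train_model: need at least 5 known-positive candidates and 5 ",
      "presumed negatives; have ", length(pos_idx), " positive(s) and ",
      length(neg_pool), " in the negative pool"
    )
  }
  n_neg <- min(length(neg_pool),
               max(5L, negatives_per_positive * length(pos_idx)))
  neg_idx <- withr::with_seed(seed, sort(sample(neg_pool, n_neg)))

  train_idx <- c(pos_idx, neg_idx)
  y <- c(rep(1L, length(pos_idx)), rep(0L, length(neg_idx)))
  x <- as.matrix(features[train_idx, FEATURE_NAMES])
  center <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  xs <- scale(x, center = center, scale = scl)
  # glmnet warns about class counts < 8; expected at desk scale
  fit <- withCallingHandlers(
    glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                   lambda = lambda, standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  structure(
    list(
      fit = fit, center = center, scale = scl, lambda = lambda,
      coefficients = stats::setNames(
        as.numeric(stats::coef(fit, s = lambda)),
        rownames(stats::coef(fit, s = lambda))
      ),
      positives = features$peak_id[pos_idx],
      negatives = features$peak_id[neg_idx]
    ),
    class = "tip_scorer"
  )
}

#' @export
print.tip_scorer <- function(x, ...) {
  cat("tip_scorer: ridge logistic on", length(FEATURE_NAMES),
      "features;", length(x$positives), "positives,",
      length(x$negatives), "negatives\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Score candidates with a fitted scorer
#'
#' @param scorer a `tip_scorer` from [train_model()].
#' @param candidates candidate table with feature columns.
#' @return `candidates` with a `probability` column in `[0, 1]`.
#' @export
score_candidates <- function(scorer, candidates) {
  stopifnot(inherits(scorer, "tip_scorer"))
  if (nrow(candidates) == 0L) {
    candidates$probability <- numeric(0)
    return(candidates)
  }
  x <- as.matrix(candidates[, FEATURE_NAMES])
  xs <- scale(x, center = scorer$center, scale = scorer$scale)
  p <- as.numeric(stats::predict(scorer$fit, newx = xs, type = "response",
                                 s = scorer$lambda))
  candidates$probability <- p
  candidates
}
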