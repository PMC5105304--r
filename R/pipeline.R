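# Pipeline orchestration: simulate -> align -> call -> score -> compare ->
# annotate, with per-stage artifacts and manifests. All stage randomness is
# derived from the master seed through stage-labeled substreams, so reruns
# with the same configuration are byte-identical.

#' Build the cohort described by a configuration
#'
#' `preset = "table2"` builds the validated-insertion cohort
#' ([build_table2_cohort()]); `preset = "null"` builds patient pairs with
#' no implanted insertions (specificity runs).
#'
#' @param config configuration list (see [default_config()]).
#' @return cohort list (reference, patients, presets, genes, exons,
#'   segments).
#' @export
build_cohort <- function(config) {
  cfg <- utils::modifyList(default_config(), config)
  if (cfg$preset == "table2") {
    build_table2_cohort(cfg$seed, chrom_length = cfg$chrom_length,
                        n_fixed_l1 = cfg$n_fixed_l1)
  } else if (cfg$preset == "null") {
    chrom_lengths <- stats::setNames(
      rep(cfg$chrom_length, cfg$null_chroms),
      paste0("chr", seq_len(cfg$null_chroms))
    )
    reference <- build_reference(derive_seed(cfg$seed, "reference"),
                                 chrom_lengths, cfg$n_fixed_l1)
    patients <- list()
    for (i in seq_len(cfg$null_patients)) {
      pid <- sprintf("N%02d", i)
      patients[[pid]] <- build_patient_pair(reference, pid)
    }
    list(reference = reference, patients = patients,
         presets = empty_implants(), genes = NULL, exons = NULL,
         segments = empty_segments())
  } else {
    stop("build_cohort: unknown preset '", config$preset, "'")
  }
}

# simulate reads for one sample with a sample-specific derived seed
simulate_sample <- function(sample, cfg) {
  simulate_vectorette_reads(
    sample,
    enzymes = vectorette_enzymes(),
    coverage = cfg$coverage,
    error_rate = cfg$error_rate,
    seed = derive_seed(cfg$seed, paste0("simulate_", sample$sample_id)),
    layout = cfg$layout,
    background_fraction = cfg$background_fraction,
    offtarget_loci = cfg$offtarget_loci,
    read_len = c(cfg$read_len_min, cfg$read_len_max),
    max_dist = cfg$max_site_dist
  )
}

# flatten a (possibly paired) read set into alignment input rows
flatten_reads <- function(readset) {
  rd <- readset$reads
  if (nrow(rd) == 0L) {
    return(data.frame(read_id = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  paired <- !is.na(rd$mate_seq)
  out <- data.frame(
    read_id = ifelse(paired, paste0(rd$read_id, "/1"), rd$read_id),
    seq = rd$seq, stringsAsFactors = FALSE
  )
  if (any(paired)) {
    out <- rbind(out, data.frame(
      read_id = paste0(rd$read_id[paired], "/2"),
      seq = rd$mate_seq[paired], stringsAsFactors = FALSE
    ))
  }
  out
}

#' Run alignment, peak calling, junction analysis and scoring for one sample
#'
#' @param readset result of [simulate_vectorette_reads()] (or a read table
#'   read from FASTQ wrapped as list(reads=, layout=, sample_id=)).
#' @param masked_reference L1-masked reference (`tip_genome`).
#' @param l1_annotation fixed-L1 annotation of the unmasked reference.
#' @param config configuration list.
#' @return list(sample_id, alignments, peaks, junction_reads, candidates,
#'   calls, scorer, n_reads).
#' @export
process_sample <- function(readset, masked_reference, l1_annotation,
                           config) {
  cfg <- utils::modifyList(default_config(), config)
  reads <- flatten_reads(readset)
  aln <- align_reads(reads, masked_reference, k = cfg$align_k,
                     max_mismatch_rate = cfg$max_mismatch_rate)
  peaks <- call_peaks(aln, min_reads = cfg$peak_min_reads,
                      max_gap = cfg$peak_max_gap)
  unmapped <- reads[aln$status == "unmapped", , drop = FALSE]
  jr <- extract_junction_reads(
    unmapped, masked_reference, peaks,
    end_len = cfg$junction_end_len, min_polyAT = cfg$junction_min_polyAT,
    cap = cfg$junction_cap, window = cfg$junction_window
  )
  feats <- compute_features(
    select_all_with_counts(peaks, jr, cfg$layout), aln, jr,
    layout = cfg$layout
  )
  candidates <- feats[feats$junction_count >= 1L, , drop = FALSE]

  # junction side and position per candidate, then consensus verdicts
  candidates$junction_side <- NA_character_
  candidates$junction_pos <- NA_integer_
  candidates$verdict <- NA_character_
  probe <- l1_three_prime_probe()
  for (i in seq_len(nrow(candidates))) {
    rows <- jr[jr$peak_id == candidates$peak_id[i], , drop = FALSE]
    cons <- build_consensus(rows)
    candidates$junction_side[i] <- cons$side
    candidates$junction_pos[i] <- if (cons$side == "left") {
      candidates$start[i]
    } else {
      candidates$end[i]
    }
    candidates$verdict[i] <- classify_consensus(
      cons, masked_reference, probe, min_identity = cfg$min_identity,
      peak = candidates[i, ]
    )$verdict
  }

  scorer <- NULL
  if (isTRUE(cfg$ml) && nrow(candidates) > 0L) {
    scorer <- train_model(
      feats, l1_annotation,
      negatives_per_positive = cfg$negatives_per_positive,
      seed = derive_seed(cfg$seed, paste0("train_", readset$sample_id))
    )
    candidates <- score_candidates(scorer, candidates)
  } else {
    candidates$probability <- rep(NA_real_, nrow(candidates))
  }

  calls <- candidates[!is.na(candidates$verdict) &
                        candidates$verdict == "insertion_supported", ,
                      drop = FALSE]
  list(
    sample_id = readset$sample_id, alignments = aln, peaks = peaks,
    junction_reads = jr, features = feats, candidates = candidates,
    calls = calls, scorer = scorer, n_reads = nrow(reads)
  )
}

# peaks with junction counts for every peak (candidates keep >=1)
select_all_with_counts <- function(peaks, junction_reads, layout) {
  cand <- select_candidates(peaks, junction_reads, layout)
  peaks$junction_count <- 0L
  m <- match(cand$peak_id, peaks$peak_id)
  peaks$junction_count[m] <- cand$junction_count
  peaks
}

#' Compare tumor and normal call sets for one patient
#'
#' Discordant calls are validated by in-silico spanning PCR against the
#' truth genomes and normal-only calls are annotated with tumor CN/LOH.
#'
#' @param pair a `tip_pair`.
#' @param blood_res,tumor_res results of [process_sample()].
#' @param config configuration list.
#' @return list(discordant, summary): `discordant` has one row per
#'   discordant call with direction, validation and CN/LOH columns.
#' @export
compare_patient <- function(pair, blood_res, tumor_res, config) {
  cfg <- utils::modifyList(default_config(), config)
  cs <- compare_call_sets(tumor_res$calls, blood_res$calls,
                          window = cfg$compare_window)
  annotate_direction <- function(calls, direction) {
    if (nrow(calls) == 0L) {
      calls$direction <- character(0)
      calls$validation <- character(0)
      calls$filled_size <- integer(0)
      calls$empty_size <- integer(0)
      return(calls)
    }
    calls$direction <- direction
    calls$validation <- NA_character_
    calls$filled_size <- NA_integer_
    calls$empty_size <- NA_integer_
    for (i in seq_len(nrow(calls))) {
      v <- insilico_validate(calls[i, ], pair$blood, pair$tumor,
                             pair$reference,
                             primer_flank = cfg$primer_flank,
                             max_amplicon = cfg$max_amplicon)
      if (v$status == "untested") {
        calls$validation[i] <- "untested"
        next
      }
      expected <- if (direction == "tumor_only") {
        v$productive_tumor && !v$productive_blood
      } else {
        v$productive_blood && !v$productive_tumor
      }
      calls$validation[i] <- if (expected) "productive" else "unproductive"
      calls$empty_size[i] <- v$empty_size
      filled <- setdiff(c(v$sizes_blood, v$sizes_tumor), v$empty_size)
      if (length(filled)) calls$filled_size[i] <- max(filled)
    }
    calls
  }
  tumor_only <- annotate_direction(cs$tumor_only, "tumor_only")
  normal_only <- annotate_direction(cs$normal_only, "normal_only")
  normal_only <- integrate_cn_loh(normal_only, pair$segments)
  if (nrow(tumor_only) > 0L) {
    tumor_only$cn <- "NT"
    tumor_only$loh <- "NT"
  } else {
    tumor_only$cn <- character(0)
    tumor_only$loh <- character(0)
  }
  discordant <- rbind(tumor_only, normal_only)
  summary <- data.frame(
    patient_id = pair$patient_id,
    tumor_tested = nrow(tumor_only),
    tumor_productive = sum(tumor_only$validation == "productive",
                           na.rm = TRUE),
    normal_tested = nrow(normal_only),
    normal_productive = sum(normal_only$validation == "productive",
                            na.rm = TRUE),
    shared = nrow(cs$shared),
    stringsAsFactors = FALSE
  )
  list(discordant = discordant, summary = summary)
}

# match a validated discordant call back to its truth insertion
match_truth <- function(call, truth, window = 500L) {
  want_somatic <- call$direction == "tumor_only"
  sel <- truth$somatic == want_somatic & truth$chrom == call$chrom &
    abs(truth$tsd_start - call$junction_pos) <= window
  if (!any(sel)) return(NULL)
  truth[which(sel)[1L], , drop = FALSE]
}

#' Annotate validated discordant calls with TPRT hallmarks
#'
#' Each validated call is matched to its truth locus; the insertion allele
#' is reconstructed there (the simulation stand-in for sequencing the
#' spanning-PCR product) and measured with [characterize_insertion()];
#' gene context comes from [gene_overlap()].
#'
#' @param cohort cohort list from [build_cohort()].
#' @param compare_results named list (per patient) from
#'   [compare_patient()].
#' @return report data.frame from [render_report()].
#' @export
annotate_cohort <- function(cohort, compare_results) {
  rows <- list()
  for (pid in names(compare_results)) {
    pair <- cohort$patients[[pid]]
    disc <- compare_results[[pid]]$discordant
    val <- disc[!is.na(disc$validation) & disc$validation == "productive", ,
                drop = FALSE]
    for (i in seq_len(nrow(val))) {
      tr <- match_truth(val[i, ], pair$truth)
      if (is.null(tr)) next
      loc <- insertion_locus(pair$reference, tr)
      ch <- characterize_insertion(loc$allele, loc$flank5, loc$flank3)
      gene <- if (!is.null(cohort$genes) && nrow(cohort$genes) > 0L) {
        gene_overlap(list(chrom = tr$chrom, pos = tr$tsd_start),
                     cohort$genes, cohort$exons)
      } else {
        list(gene = NA_character_, feature = "intergenic", distance = Inf)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = pid, chrom = tr$chrom,
        junction5 = tr$junction5, junction3 = tr$junction3,
        strand = ch$strand, element_length = ch$element_length,
        tsd_length = ch$tsd_length,
        inversion_length = ch$inversion_length,
        polyA_length = ch$polyA_length,
        gene = if (gene$feature == "intergenic") "." else gene$gene,
        cn = val$cn[i], loh = val$loh[i],
        validation = val$validation[i],
        somatic = val$direction[i] == "tumor_only",
        stringsAsFactors = FALSE
      )
    }
  }
  annotated <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), chrom = character(0),
               junction5 = integer(0), junction3 = integer(0),
               strand = character(0), element_length = integer(0),
               tsd_length = integer(0), inversion_length = integer(0),
               polyA_length = integer(0), gene = character(0),
               cn = character(0), loh = character(0),
               validation = character(0), somatic = logical(0),
               stringsAsFactors = FALSE)
  render_report(annotated)
}

stage_manifest <- function(outdir, stage, params, files) {
  files <- files[file.exists(files)]
  manifest <- list(
    stage = stage,
    parameters = params,
    outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files)))
  )
  yaml::write_yaml(manifest,
                   file.path(outdir, paste0("manifest_", stage, ".yaml")))
}

#' Run the full TIPseq analysis pipeline
#'
#' Executes simulate -> align -> call/score -> compare -> annotate on the
#' cohort described by `config`, optionally writing per-stage artifacts and
#' manifests under `outdir`. Fully deterministic for a fixed configuration.
#'
#' @param config configuration list ([default_config()] /
#'   [read_config()]).
#' @param outdir output directory for artifacts; NULL keeps everything in
#'   memory.
#' @param cohort optional pre-built cohort (overrides `config$preset`).
#' @param through last stage to execute: "simulate", "call" (covers
#'   align/call/score, which share one pass), "compare" or "annotate".
#' @return list(cohort, samples, comparisons, report, summary,
#'   table1): `summary` holds the headline validated counts. Earlier
#'   `through` values return the prefix of this list.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         cohort = NULL,
                         through = c("annotate", "compare", "call",
                                     "simulate")) {
  through <- match.arg(through)
  cfg <- utils::modifyList(default_config(), config)
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)
  if (is.null(cohort)) cohort <- build_cohort(cfg)
  reference <- cohort$reference
  masked <- mask_reference(reference)

  # --- simulate ---------------------------------------------------------
  readsets <- list()
  for (pid in names(cohort$patients)) {
    pair <- cohort$patients[[pid]]
    readsets[[pair$blood$sample_id]] <- simulate_sample(pair$blood, cfg)
    readsets[[pair$tumor$sample_id]] <- simulate_sample(pair$tumor, cfg)
  }
  if (!is.null(outdir)) {
    write_fasta(reference, file.path(outdir, "reference.fasta"))
    if (nrow(reference$l1_annotation) > 0L) {
      ann <- reference$l1_annotation
      ann$name <- ann$id
      write_bed(ann, file.path(outdir, "l1_annotation.bed"))
    }
    if (!is.null(cohort$genes) && nrow(cohort$genes) > 0L) {
      write_genes_gff(cohort$genes, cohort$exons,
                      file.path(outdir, "genes.gff3"))
    }
    truth_all <- do.call(rbind, lapply(cohort$patients, function(p) {
      if (nrow(p$truth) == 0L) return(NULL)
      cbind(patient_id = p$patient_id,
            p$truth[, names(empty_implants())],
            cn = p$truth$cn, loh = p$truth$loh)
    }))
    if (!is.null(truth_all)) {
      utils::write.table(truth_all, file.path(outdir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (nrow(cohort$segments %||% empty_segments()) > 0L) {
      write_segments(cohort$segments, file.path(outdir, "segments.tsv"))
    }
    fq_files <- character(0)
    for (sid in names(readsets)) {
      fq_files <- c(fq_files, write_fastq(
        readsets[[sid]]$reads,
        file.path(outdir, paste0(sid, ".fastq"))
      ))
    }
    stage_manifest(outdir, "simulate",
                   cfg[c("seed", "preset", "coverage", "error_rate",
                         "layout", "background_fraction")],
                   c(file.path(outdir, c("reference.fasta",
                                         "l1_annotation.bed", "genes.gff3",
                                         "truth.tsv", "segments.tsv")),
                     fq_files))
  }

  if (through == "simulate") {
    return(invisible(list(cohort = cohort, readsets = readsets)))
  }

  # --- align / call / score (per sample) --------------------------------
  samples <- list()
  for (sid in names(readsets)) {
    samples[[sid]] <- process_sample(readsets[[sid]], masked,
                                     reference$l1_annotation, cfg)
  }
  if (!is.null(outdir)) {
    call_files <- character(0)
    for (sid in names(samples)) {
      s <- samples[[sid]]
      f_aln <- file.path(outdir, paste0(sid, "_alignments.tsv"))
      utils::write.table(s$alignments, f_aln, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      f_cand <- file.path(outdir, paste0(sid, "_candidates.tsv"))
      utils::write.table(
        s$candidates[, setdiff(names(s$candidates), "junction_side")],
        f_cand, sep = "\t", quote = FALSE, row.names = FALSE
      )
      call_files <- c(call_files, f_aln, f_cand)
      if (nrow(s$peaks) > 0L) {
        f_peaks <- file.path(outdir, paste0(sid, "_peaks.bed"))
        pk <- s$peaks
        pk$name <- pk$peak_id
        pk$score <- pk$max_coverage
        write_bed(pk, f_peaks)
        call_files <- c(call_files, f_peaks)
      }
      if (!is.null(s$scorer)) {
        f_coef <- file.path(outdir, paste0(sid, "_model.txt"))
        writeLines(
          paste(names(s$scorer$coefficients),
                format(s$scorer$coefficients, digits = 8), sep = "\t"),
          f_coef
        )
        call_files <- c(call_files, f_coef)
      }
    }
    stage_manifest(outdir, "call",
                   cfg[c("peak_min_reads", "peak_max_gap",
                         "junction_end_len", "junction_min_polyAT",
                         "junction_cap", "ml")],
                   call_files)
  }

  if (through == "call") {
    return(invisible(list(cohort = cohort, samples = samples)))
  }

  # --- compare ----------------------------------------------------------
  comparisons <- list()
  for (pid in names(cohort$patients)) {
    pair <- cohort$patients[[pid]]
    comparisons[[pid]] <- compare_patient(
      pair, samples[[pair$blood$sample_id]],
      samples[[pair$tumor$sample_id]], cfg
    )
  }
  table1 <- do.call(rbind, lapply(comparisons, `[[`, "summary"))
  rownames(table1) <- NULL
  if (through == "compare") {
    if (!is.null(outdir)) {
      utils::write.table(table1, file.path(outdir, "table1_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(invisible(list(cohort = cohort, samples = samples,
                          comparisons = comparisons, table1 = table1)))
  }

  # --- annotate ---------------------------------------------------------
  report <- annotate_cohort(cohort, comparisons)
  summary <- list(
    validated_normal_only = sum(table1$normal_productive),
    validated_tumor_only = sum(table1$tumor_productive),
    normal_only_loh_Y = sum(report$loh == "Y" & !is.na(report$loh) &
                              report$category == "blood_specific"),
    n_patients = nrow(table1),
    n_reads = sum(vapply(samples, `[[`, numeric(1), "n_reads"))
  )
  if (!is.null(outdir)) {
    disc_all <- do.call(rbind, lapply(names(comparisons), function(pid) {
      d <- comparisons[[pid]]$discordant
      if (nrow(d) == 0L) return(NULL)
      cbind(patient_id = pid, d)
    }))
    if (!is.null(disc_all)) {
      utils::write.table(disc_all, file.path(outdir, "discordant.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(table1, file.path(outdir, "table1_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report, file.path(outdir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(summary, file.path(outdir, "summary.yaml"))
    stage_manifest(outdir, "report",
                   cfg[c("compare_window", "primer_flank", "max_amplicon")],
                   file.path(outdir, c("discordant.tsv",
                                       "table1_summary.tsv", "report.tsv",
                                       "summary.yaml")))
  }
  invisible(list(cohort = cohort, samples = samples,
                 comparisons = comparisons, report = report,
                 summary = summary, table1 = table1))
}
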