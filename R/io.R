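# Format adapters. In memory everything is 1-based inclusive; BED is
# converted to 0-based half-open at the disk boundary. FASTA/FASTQ go
# through Biostrings; FASTQ input is structurally validated first so a
# malformed record is rejected with its line number.

#' Write chromosome sequences as FASTA
#' @param chroms named character vector (or `tip_genome`).
#' @param path output file.
#' @export
write_fasta <- function(chroms, path) {
  if (inherits(chroms, "tip_genome")) chroms <- chroms$chromosomes
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(chroms), path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path input file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write reads as FASTQ (two files for paired layout)
#'
#' @param reads read table from [simulate_vectorette_reads()].
#' @param path output path; paired layouts write `_1.fastq`/`_2.fastq`
#'   siblings.
#' @return character vector of the file(s) written.
#' @export
write_fastq <- function(reads, path) {
  fq <- function(ids, seqs, quals, file) {
    x <- Biostrings::BStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, file, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
    file
  }
  paired <- nrow(reads) > 0 && any(!is.na(reads$mate_seq))
  if (!paired) {
    return(fq(reads$read_id, reads$seq, reads$qual, path))
  }
  base <- sub("\\.fastq$", "", path)
  c(
    fq(paste0(reads$read_id, "/1"), reads$seq, reads$qual,
       paste0(base, "_1.fastq")),
    fq(paste0(reads$read_id, "/2"), reads$mate_seq, reads$mate_qual,
       paste0(base, "_2.fastq"))
  )
}

#' Read FASTQ with structural validation
#'
#' @param path FASTQ file.
#' @return data.frame(read_id, seq, qual).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("read_fastq: ", path, ": truncated record at line ",
         length(lines) %/% 4L * 4L + 1L)
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("read_fastq: ", path, ": missing '@' header at line ",
         (bad[1L] - 1L) * 4L + 1L)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop("read_fastq: ", path, ": missing '+' separator at line ",
         (bad[1L] - 1L) * 4L + 3L)
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop("read_fastq: ", path, ": quality length differs from sequence ",
         "length at line ", (bad[1L] - 1L) * 4L + 4L)
  }
  data.frame(
    read_id = sub("^@", "", sub("\\s.*$", "", hdr)),
    seq = toupper(seqs), qual = quals, stringsAsFactors = FALSE
  )
}

#' Write intervals as BED (0-based half-open on disk)
#'
#' @param df data.frame with chrom, start, end (1-based inclusive) and
#'   optional name/score/strand columns.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(
    chrom = df$chrom, start = df$start - 1L, end = df$end,
    name = df$name %||% df$id %||% ".",
    score = df$score %||% 0L,
    strand = df$strand %||% ".",
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED into 1-based inclusive intervals
#' @param path BED file.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "name"
  if (ncol(df) >= 5L) names(df)[5L] <- "score"
  if (ncol(df) >= 6L) names(df)[6L] <- "strand"
  df$start <- df$start + 1L
  df
}

#' Write/read the CN/LOH segment table
#'
#' Tab-separated: chrom, start, end, CN, LOH (1-based inclusive).
#' @param segments segment data.frame.
#' @param path file path.
#' @export
write_segments <- function(segments, path) {
  out <- segments[, c("chrom", "start", "end", "copy_number", "loh")]
  out$loh <- ifelse(out$loh, "Y", "N")
  names(out) <- c("chrom", "start", "end", "CN", "LOH")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  data.frame(
    chrom = df$chrom, start = as.integer(df$start),
    end = as.integer(df$end), copy_number = as.integer(df$CN),
    loh = df$LOH == "Y", stringsAsFactors = FALSE
  )
}

#' Write a gene model as GFF3 (gene + exon features)
#' @param genes,exons gene/exon tables as used by [gene_overlap()].
#' @param path output file.
#' @export
write_genes_gff <- function(genes, exons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    writeLines(sprintf("%s\ttipseqr\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chrom[i], genes$start[i], genes$end[i],
                       genes$strand[i], genes$gene[i]), con)
    e <- exons[exons$gene == genes$gene[i], , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      writeLines(sprintf("%s\ttipseqr\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         e$chrom[j], e$start[j], e$end[j],
                         genes$strand[i], genes$gene[i]), con)
    }
  }
  invisible(path)
}

#' Read a GFF3 gene model written by [write_genes_gff()]
#' @param path GFF3 file.
#' @export
read_genes_gff <- function(path) {
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)
  if (length(bad)) {
    stop("read_genes_gff: ", path, ": malformed record at line ", bad[1L])
  }
  df <- as.data.frame(do.call(rbind, f), stringsAsFactors = FALSE)
  names(df) <- c("chrom", "source", "type", "start", "end", "score",
                 "strand", "phase", "attr")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  g <- df[df$type == "gene", , drop = FALSE]
  e <- df[df$type == "exon", , drop = FALSE]
  list(
    genes = data.frame(gene = sub("^ID=", "", g$attr), chrom = g$chrom,
                       start = g$start, end = g$end, strand = g$strand,
                       stringsAsFactors = FALSE),
    exons = data.frame(gene = sub("^Parent=", "", e$attr), chrom = e$chrom,
                       start = e$start, end = e$end,
                       stringsAsFactors = FALSE)
  )
}

# ---- pipeline configuration -------------------------------------------

#' Default pipeline configuration
#'
#' All stage parameters with their package defaults; [read_config()]
#' rejects keys outside this schema.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    preset = "table2",
    chrom_length = 120000L,
    n_fixed_l1 = 7L,
    null_patients = 1L,
    null_chroms = 2L,
    coverage = 30,
    error_rate = 0.002,
    layout = "single",
    background_fraction = 0.05,
    offtarget_loci = 12L,
    read_len_min = 75L,
    read_len_max = 100L,
    max_site_dist = 2500L,
    align_k = 20L,
    max_mismatch_rate = 0.03,
    peak_min_reads = 3L,
    peak_max_gap = 100L,
    junction_end_len = 35L,
    junction_min_polyAT = 6L,
    junction_cap = 200L,
    junction_window = 500L,
    min_identity = 0.9,
    ml = TRUE,
    negatives_per_positive = 1L,
    compare_window = 200L,
    primer_flank = 20L,
    max_amplicon = 9000L
  )
}

#' Read a YAML pipeline configuration
#'
#' Unknown keys are rejected; missing keys take package defaults.
#'
#' @param path YAML file.
#' @return full configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("read_config: unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  }
  cfg[names(user)] <- user
  cfg
}

#' Write a pipeline configuration as YAML
#' @param config configuration list.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
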