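Package: tipseqr
Title: Transposon Insertion Profiling by Sequencing (TIPseq) Analysis for
    Somatic LINE-1 Insertion Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of vectorette-PCR based transposon
    insertion profiling (TIPseq) experiments targeting the 3' end of active
    LINE-1 (L1Hs) retrotransposons. Provides a synthetic-data generator that
    implants polymorphic and somatic L1 insertions with target-primed reverse
    transcription hallmarks (target site duplication, 5' truncation, 5'
    inversion, polyA tail) into toy diploid genomes and emits
    restriction-enzyme-shaped amplicon reads; an internal seed-and-extend
    read aligner against an L1-masked reference; coverage-peak calling with
    split-end junction-read recovery and polyA filtering; a five-feature
    logistic candidate scorer trained within-sample on known L1 copies;
    matched tumor-normal discordance analysis with in-silico spanning-PCR
    validation and copy-number / loss-of-heterozygosity integration; and
    annotation of validated insertions with retrotransposition hallmarks and
    gene context.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    glmnet,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
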