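---
title: "Calling somatic LINE-1 insertions from TIPseq data: models and methods"
author: "tipseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling somatic LINE-1 insertions from TIPseq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipseqr)
```

## The assay and what the package models

Transposon Insertion Profiling by sequencing (TIPseq) locates copies of the
human-specific LINE-1 retrotransposon subfamily (L1Hs) by selective
amplification of their 3' junctions. Genomic DNA is digested in six parallel
reactions (AseI, BspHI, BstYI, HindIII, NcoI, PstI), vectorette adapters are
ligated to the fragment ends, and a primer seated in the L1 3'UTR drives
ligation-mediated PCR across the element's polyA tail into the unique flanking
genome. Amplicons are sheared to ~300 bp and sequenced with 75-100 bp reads.
Because every amplicon starts at the same 3'UTR anchor and ends at the first
downstream restriction site, read depth mapped against the reference is
maximal immediately beside the junction and steps downward as the shorter
enzyme amplicons run out — the triangular pileup that identifies an L1 3' end.

`tipseqr` implements both of the analytical routes such data are analyzed
with, plus a synthetic-data generator so that every stage is testable without
any external download:

1. **Peak + junction analysis** — reads are aligned to an L1-masked
   reference; coverage peaks are ranked by maximum per-base depth;
   unmappable reads are split-end mapped (35 bp from each end), filtered for
   a polyA/polyT run, assembled into an anchored consensus, and the
   consensus is compared to both the genome and an L1-3'+polyA probe.
2. **Five-feature scoring** — candidate sites (peaks with junction
   evidence) receive a probability from a ridge-regularized logistic model
   on peak width, peak depth, variant index, polyA tail purity, and
   junction read count, trained within each sample on peaks at known
   (annotated) L1 copies.

Matched tumor and blood call sets are compared in both directions, each
discordant call is validated by in-silico spanning PCR, normal-only calls
are annotated with tumor copy-number / loss-of-heterozygosity (CN/LOH)
segments, and validated insertions are characterized for the hallmarks of
target-primed reverse transcription (TPRT): target site duplication (TSD),
5' truncation, 5' inversion, and polyA tail.

## The synthetic element and genome

The packaged consensus element is a fixed, deterministic 6059 bp sequence —
the length of the longest insertion the pipeline is expected to report, so a
full-length implant is exactly one consensus copy. The amplification anchor
occupies element positions `r l1_consensus()$anchor_start`-`r
l1_consensus()$anchor_end`, i.e. 340-359 bp from the 3' terminus, inside the
final 10% of the element. Any insertion whose non-inverted 3' extent is at
least 360 bp therefore remains amplifiable, which covers every preset
insertion (shortest: 684 bp). The consensus's first and last bases are pinned
to non-T/non-A so that tail detection and strand assignment in
`characterize_insertion()` are exact rather than ambiguous by one base.

An insertion allele is constructed as

```
flank5 | TSD | [revcomp(5' segment)] + 3' element portion + polyA | TSD | flank3
```

with the whole body reverse-complemented for minus-strand insertions. Both
junction coordinates sit inside the duplicated interval, so
`tsd_length == |junction5 - junction3| + 1`; this is the only convention
consistent with all nine fully printed coordinate/TSD pairs of the validated
panel, and `measure_tsd()` implements it directly. No strand-to-coordinate
ordering rule is imposed: the panel itself contains minus-strand rows with
both junction orders.

## The simulator: what it emulates, and what it does not

For every L1 3' end on a haplotype — annotated fixed copies and implants
alike — and each enzyme, the simulator emits the amplicon from the anchor
through the tail and flank to the first recognition site (truncated, with a
log entry, at 2.5 kb when no site occurs), shears it into ~300 +- 60 bp
fragments, and samples reads. Defaults, chosen once to mirror the assay
conditions:

| parameter | default | rationale |
|---|---|---|
| coverage | 30 | junction depth summed over enzymes and haplotypes; heterozygous junctions see ~15x |
| read length | 75-100 bp | the trimmed-read envelope of the assay |
| error rate | 0.002/bp | typical Illumina substitution rate; substitutions only |
| paired insert | 450 +- 50 bp | the size-selection target of the library protocol |
| background | 5% | uniform off-assay reads |
| off-target loci | 12/sample | vectorette mispriming stacks (below) |

Heterozygosity is modeled with two haplotypes per sample: implants ride on
haplotype 1, haplotype 2 is the unmodified reference. Copy-neutral LOH
replaces the carrier haplotype's segment with the insertion-free copy; a CN 1
deletion excises it. Read depth then behaves as in the assay: a heterozygous
junction has half the depth of a homozygous fixed copy, and a tumor that lost
the carrier allele produces no junction reads at all.

**Off-target loci.** Uniform background reads at desk scale essentially never
stack three deep, yet the within-sample classifier needs presumed-negative
peaks and real vectorette data is full of non-specific amplification (the
source of the many candidate loci that validation assays reject). The
simulator therefore places a configurable number of mispriming amplicons per
sample — localized read stacks with no L1 junction structure. They form
peaks, never candidates, and constitute the presumed-negative training pool.

Not modeled, deliberately: PCR duplicates, GC bias, quality-score decay,
chimeric amplicons, and indel errors. The aligner is correspondingly ungapped.
Passing tests on this generator demonstrate the pipeline logic — peak
geometry, junction recovery, discordance bookkeeping, validation arithmetic —
not robustness to the full error structure of real libraries; real-data users
should expect TSD detection in particular to need the fuzziness this package's
exact-duplication rule forgoes.

## Alignment

The internal aligner is exact k-mer seeding (k = 20) with ungapped extension,
scoring mismatches, N never matching. The mismatch allowance is 3 per 100
aligned bases. With `max_mm + 2` seeds spread across a read, every placement
within `max_mm + 1` mismatches is guaranteed to be seeded (pigeonhole), so
the unique/multi/unmapped decision provably equals an exhaustive scan — the
test suite checks this against a brute-force oracle. "Unique" additionally
requires the best placement to beat the runner-up by at least 2 mismatches,
a deliberately conservative stand-in for mapping quality that the
one-unique-end junction rule depends on. The choice of aligner is treated as
interchangeable infrastructure; nothing downstream depends on more than
(coordinates, strand, mismatch count, status).

## Junction reads, consensus, classification

From each unmappable read, both 35 bp ends are aligned separately; reads with
exactly one uniquely aligning end are junction candidates, and the unaligned
overhang must contain a run of at least six consecutive A or six consecutive
T — both bases, because pre-classification the insertion strand is unknown.
The run may occur anywhere in the overhang (the alternative — requiring it to
be terminal — is stricter; the choice is isolated in one filter and flagged
for sensitivity analysis). Junction reads attach to the nearest peak within
500 bp, and each peak keeps at most 200, in deterministic
(anchor coordinate, read id) order rather than by sampling, so runs are
reproducible.

Because every overhang abuts its own anchor alignment, the center-star
multiple alignment of overhangs degenerates to coordinate anchoring: each
overhang is placed at the genomic offsets implied by its anchor, columns are
majority-voted (ties broken A < C < G < T), and the consensus is the longest
contiguous column run with at least two supporting reads. The consensus is
then split by finding the longest terminal block that occurs in the locus
neighborhood — a binary search tolerating max(1, 2% of block length)
mismatches, so a single voting error in a terminal column cannot hide the
block. This locates the junction boundary precisely even beside the polyA
tail, where a local aligner tends to over-extend into the homopolymer. A
consensus is `insertion_supported` when the non-genomic remainder matches
the L1-3'+polyA probe (either orientation, query-coverage identity >= 0.9)
and the genomic block either passes a genome-wide uniqueness test (>= 20 bp)
or, for shorter blocks (12-19 bp, typical when a peak holds only a handful
of junction reads), is consistent with a peak locus already pinned by
uniquely aligned reads; `reference_only` when the genome absorbs >= 95% of
it; `ambiguous` otherwise.

## The five features and the scorer

* **peak width** and **peak depth** (maximum per-base coverage);
* **variant index** — interpreted here as the mean per-read mismatch
  fraction over uniquely aligned reads in the peak interval (the term is not
  otherwise pinned down; the definition is isolated in one function);
* **polyA tail purity** — the A (or T) fraction in a 20 bp window around the
  overhang's longest mononucleotide run, averaged over the peak's junction
  reads (again a declared interpretation, isolated for substitution);
* **junction read count** (read pairs in paired layout).

Candidates are exactly the peaks with at least one junction read (pair).
Training is within-sample: positives are candidate peaks within 500 bp of an
annotated L1 3' end; presumed negatives are sampled (seeded) from peaks more
than 10 kb from any annotated element, preferring junction-free peaks so that
a genuine novel insertion among the far peaks cannot label itself negative.
The model is a ridge-regularized logistic fit (lambda = 0.01) on standardized
features — the simplest probabilistic model consistent with "five features
in, probability out". No probability threshold is hard-coded: downstream
comparison consumes classification verdicts, and probabilities are reported
for ranking, mirroring how low-probability candidate lists were handled in
practice (reported, then tested by PCR).

## Discordance, validation, CN/LOH

Tumor and normal call sets are partitioned with a 200 bp matching window
(the coordinate tolerance is not dictated by anything in the assay; 200 bp
comfortably exceeds peak-edge jitter at these depths). Shared calls are never
validated — only discordant candidates are tested, which is how the original
assays were budgeted. In-silico spanning PCR picks unique exact 20-mers from
the reference on both sides of the junction (the desk stand-in for primer
design), measures product sizes on every haplotype of both samples, and calls
a sample productive when it yields a product more than 20 bp larger than the
empty-site product (capped at 9 kb, comfortably above a full-length filled
site of ~6.4 kb). Three properties follow by construction and are tested:
a heterozygous blood-only implant is productive in blood only; a locus with
no insertion is unproductive everywhere; and filled minus empty size equals
`element_length + polyA_length + tsd_length` exactly. Loci inside fixed L1
copies come back `untested` (no unique primer within the search radius),
which matches how repetitive loci behave under real primer design.

Normal-only calls are annotated with the CN/LOH state of the overlapping
tumor segment (`NT` when none overlaps). In the preset cohort every
blood-specific insertion is covered by a matching segment — one per locus,
except a whole-chromosome copy-neutral LOH on chr8 of patient 897 covering
two insertions at once.

## Hallmark characterization

`characterize_insertion()` takes the modified-locus sequence plus the two
pre-insertion flanks, detects the TSD as the longest exactly duplicated
flank suffix/prefix pair, strips the tail (>= 5 A, a separate constant from
the junction filter's >= 6), assigns strand from which end carries the tail,
and decomposes the element: the longest common suffix with the consensus
gives candidate 3' extents, and the largest extent whose remaining 5'
portion reverse-complements onto the adjacent upstream consensus segment
wins. Scanning extents downward matters: a chance one-base agreement between
the inverted segment's edge and the consensus can inflate the common suffix,
and the joint check resolves it. Recovery is exact — strand, element length,
inversion length, polyA length, TSD — over randomized implants at zero error
rate, including the published somatic configuration (1839 bp element, 662 bp
inversion, 10 bp TSD); the acceptance suite runs 200 such round trips.

In pipeline runs the allele that gets characterized is reconstructed at the
truth locus — the simulation's stand-in for Sanger-sequencing the validation
product. Splitting a filled/empty product pair instead was prototyped and
rejected: when a flank base coincides with the adjacent element or TSD base,
the decomposition is ambiguous by a base, which is a genuine property of
product-only data rather than a fixable defect. Real-data users supply their
own sequenced allele and flanks.

## The preset cohort and problem sizes

The validated-insertion panel ships as `table2_presets()`: 11 blood-specific
insertions across six of seven primary-pair patients (8 fully sequenced, 3
with an uncharacterized 5' end, flagged `partial` and given configured
defaults of 3000 bp / 15 bp TSD rather than invented measurements) and one
somatic insertion in secondary patient 083. Printed junction coordinates are
folded onto 120 kb toy chromosomes modulo the usable length, preserving each
pair's offset — so the TSD arithmetic survives the mapping unchanged, and the
insertion found in two unrelated patients lands at the same folded locus in
both. Named genes become synthetic gene models (two terminal exons, insertion
intronic); unnamed rows stay intergenic.

The full cohort is ten patient pairs sharing one seven-chromosome, 840 kb
reference with one fixed L1 per chromosome — about 70,000 reads per run,
roughly two minutes end-to-end on one core. These sizes were chosen as the
smallest instance on which every qualitative outcome of the study design
(11 blood-only validated, 1 somatic validated, LOH explaining every
blood-only call, no false validated discordants across seeds) is stable;
specificity checks run twenty seeds of a smaller two-chromosome null cohort.

## Reproducibility

All randomness descends from one master seed through stage- and
sample-labeled substreams (`derive_seed()`), so any stage can be rerun
independently and two runs with the same configuration are byte-identical —
manifests with md5 content hashes are written per stage to make regression
comparisons trivial. The command-line wrapper (`inst/cli/tipseqr-cli.R`)
exposes the stages as subcommands over a single YAML configuration; stage
subcommands recompute their (deterministic, cheap) upstream state from the
configuration rather than re-parsing artifacts.

## Known limitations

* Exact-duplication TSD detection and exact-20-mer primers are right for the
  error-free generator, optimistic for real data.
* No gapped alignment: an indel-bearing junction read is simply lost.
* Single- and paired-end layouts are supported, but pair information is used
  only for junction-unit counting, not for insert-size evidence.
* Gene context reports containment and distance only — no splice-aware
  consequence calls.
* The scorer is linear in five features by design; it will not learn
  interactions (none are needed to separate the generator's classes, and
  nothing richer is identifiable from cohorts this small).
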