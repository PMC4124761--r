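---
title: "Profiling small RNA classes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling small RNA classes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smallRNAsig)
```

## The analysis in one paragraph

A small RNA sequencing library mixes several RNA classes with very
different biology: ~22 nt miRNAs excised from hairpin precursors,
fragments of structural RNAs (rRNA, snoRNA, tRNA, scRNA, snRNA),
26–31 nt piRNAs transcribed from single-strand genomic clusters that are
rich in retrotransposon repeats, and 18–23 nt repeat-derived endogenous
siRNAs. `smallRNAsig` turns raw reads into per-class quantities in five
stages: (1) adapter trimming and clean-read filtering; (2) collapsing
identical reads into *tags* (sequence + copy number); (3) exhaustive
perfect-match mapping of every tag to both genome strands; (4)
hierarchical annotation in the fixed priority order
**miRNA > rRNA/snoRNA/tRNA/scRNA/snRNA > piRNA > endo-siRNA**; (5)
class-specific quantification — RPM-normalised miRNA signatures and
sample clustering, hit-weighted piRNA genome landscapes with
repeat-family enrichment, and a three-criterion endo-siRNA screen.

## Clean reads and tags

Reads are trimmed by a semi-global alignment of the 3' adapter (any start
position, may run off the read end, overlap ≥ 6 nt, mismatch fraction
≤ 0.1, best score = matches − mismatches, ties toward the longest trim).
A 5' adapter can be trimmed or treated as a contaminant flag; single-end
small-RNA protocols normally only read through the 3' adapter, so 5'
handling is off by default. "Clean" reads then satisfy: length within
18–40 nt (the gel-selected insert range; anything under 18 nt is
inadequate), no ambiguous N, and mean Phred ≥ 20. *Low-quality* and
*contaminant* have no universal definition; the mean-Phred-20/no-N rule
and the optional user-supplied contaminant list are this package's
choices, both exposed as parameters. Each rejected read is charged to
exactly one category so the ledger always balances:
raw = clean + contaminant + length + quality.

Collapsing is lossless bookkeeping: one tag per distinct sequence, counts
summing to the clean-read total. All downstream statistics operate on
tags, which is what makes the multi-mapper weighting below well defined.

## Perfect-match mapping

Only perfect matches are retained, so mapping is exact substring search,
not alignment. The matcher reports **every** occurrence of a tag on both
strands — no hit-count cap — because the weighted count
ω = #Reads/#Hits is only meaningful when #Hits is the true genome-wide
occurrence count. Coordinates are 0-based half-open internally (BED
convention) and 1-based only in GFF3 I/O. A tag equal to its own reverse
complement is reported on both strands at the same locus; this
convention matters because it doubles that tag's #Hits and is therefore
stated, tested, and mirrored by the naive-scan oracle used in the test
suite. Mapping percentages are rounded half-up to two decimals, the
convention of printed sequencing summary tables.

## Hierarchical annotation

Each mapped tag is assigned the highest-priority class overlapped by
*any* of its hits, mirroring read-level database annotation where any
hit classifies the read. Database-search annotation (BLAST against
class-specific databases) is replaced here by interval overlap against
user-supplied per-class tracks: deterministic, version-pinnable, and
testable; tracks can be regenerated from miRBase/Rfam/RepeatMasker
coordinates. An overlap counts when it covers ≥ 80% of the tag length
(`min_overlap_frac`; no published threshold exists, 0.8 keeps a 22-mer
from being claimed by a 5-base brush with a track). Strand rules: miRNA
and structural classes require same-strand overlap; piRNA clusters are
single-strand annotations but cluster-proximal signal is sometimes
plotted on both strands, so strand-agnostic piRNA overlap is available
behind `pirna_stranded = FALSE` (default: same-strand). Ties are broken
by largest overlap, then class order (within the miRNA tier the mature
arm outranks its hairpin, so the more specific locus is recorded), then
lexicographic locus id — classification is therefore invariant to input
order. Endo-siRNA is assigned last and by rule, not track (below);
everything left is `unannotated`.

## miRNA quantification and signatures

miRNA-classified tags are counted onto mature arms (full count to each
distinct mature the tag hits; hairpin-only tags go to a flagged bucket).
RPM uses the per-sample total of miRNA-annotated reads as denominator —
the natural "within each sample" denominator for a miRNA-only analysis —
so each RPM column sums to exactly 1e6; total genome-mapped reads is
available as an alternative (`mirna_denominator = "genome"`). Expression
is called at RPM ≥ 1. The log2 layer uses no pseudocount by default
because the RPM ≥ 1 filter precedes any log-scale analysis; clustering
uses log2(RPM + 1) so that unexpressed-in-some-sample features stay
finite.

A focal sample's signature is the set of miRNAs expressed there with
fold change ≥ 2 against **each** other sample (conjunction; comparing
against the mean of the others is available via `vs = "mean"`). Fold
changes are computed on the RPM scale as
RPM_focal / max(RPM_other, ε) with ε = 0.5 RPM. The guard is a
*denominator floor*, not an additive shift, so that an exact 2-fold
difference (10 vs 5 RPM) passes at threshold 2 while zero denominators
stay finite; an additive ε on both sides would silently fail exact-fold
boundary cases. Samples are clustered with average linkage on
1 − Pearson correlation, the standard geometry of expression heat maps;
tests assert topology on constructed data, never merge heights.

## Weighted piRNA landscapes

piRNAs are heavily multi-mapping (clusters are repeat-rich), so each
tag's count is spread evenly over its hits: ω = count / #Hits per hit.
This conserves mass exactly — summed over all hits a tag contributes its
read count, and the genome-wide weighted total equals the piRNA read
count to floating-point precision (asserted at 1e-9). The genome
distribution bins each hit's 5' end (strand-aware) and keys plus and
minus strands separately; bin size defaults to 1 kb on toy genomes
(~100 kb is appropriate on a full mammalian genome). Samples whose
weighted piRNA total falls below `pirna_floor` are excluded from the
landscape output, mirroring the practice of dropping libraries with
negligible piRNA signal from such plots.

Repeat-family enrichment between two samples compares each family's
(in-family, out-of-family) weighted counts with Fisher's exact test on
integer-rounded weights, Benjamini–Hochberg-corrected across families.
No published description of the original enrichment statistic exists;
Fisher/BH was chosen for small-table robustness, and the rounding of
fractional weights is documented as an approximation.

## The endo-siRNA screen

A tag is an endo-siRNA candidate iff (1) its length is 18–23 nt, (2) it
perfectly matches the genome, and (3) it is repeat-derived (≥ 50% of the
tag covered by a repeat interval at some hit; the threshold is a package
choice, exposed as `sirna_repeat_overlap_frac`). The published criteria
do not mention excluding higher classes, but the annotation hierarchy
places endo-siRNA last, so a tag already claimed by miRNA, a structural
class or piRNA is excluded — anything else would double-count 22 nt
miRNAs as siRNAs. Length profiles sum the per-tag weighted count
(count/#Hits, one term per tag) and scale to tag count per 10 million
total genome-mapped reads; the per-sample mapped total is the only
denominator available at this pipeline stage, and it is config-exposed.

## The synthetic-data generator

The generator exists so that every stage can be tested against known
ground truth; its defaults encode the study conditions the pipeline is
designed around, and they are not tuned per test.

* **Genome**: 100 kb single chromosome of i.i.d. random sequence, with
  mutually non-overlapping class loci: 20 miRNA hairpins (80 nt, mature
  arms nested at both ends, 5p always, 3p with probability 0.7),
  16 structural loci across rRNA/snoRNA/tRNA/scRNA/snRNA, 6 piRNA
  clusters (1.2 kb, single-strand, usually wrapped in an ERV1/2/3
  repeat, in identical-sequence pairs so genuine multi-mapping piRNA
  reads exist whose hits are all cluster hits), 15 free-standing repeats
  across ERV1/ERV2/ERV3/LINE/SINE that double as endo-siRNA source
  loci, and 8 intergenic windows for background reads. Disjoint
  placement makes every read's true class unambiguous, which is what
  lets recovery tests demand exactness; overlap handling in the
  annotator is exercised separately with hand-built fixtures.
* **Reads**: class drawn from the profile's mixture (multinomial),
  locus by per-locus weights, length from per-class models — miRNA
  peaks at 22–23 nt, piRNA at 27–30 nt, endo-siRNA at 20–22 nt,
  structural fragments broad at 24–33 nt, background 15–34 nt so the
  <18 nt filter fires. piRNA reads are emitted from the cluster's
  annotated strand only. The full 3' adapter is ligated and the
  molecule truncated to 40 machine cycles, as in real read-through
  small-RNA libraries; errors are substitutions only, so a perfect-match
  failure is their only possible consequence — matching the
  perfect-match-only retention rule. Qualities are a constant Phred 37;
  quality filtering is exercised by constructed fixtures instead.
* **Five default profiles** (ESC/SSC/GC/ST/MSC-like) encode only the
  qualitative contrasts the analysis is meant to expose, since no
  numeric per-sample mixtures are published: miRNA ~60% of annotated
  reads everywhere except the germ-cell library, where piRNA is modal
  (55%); piRNA ordered GC > SSC > ESC > ST > MSC; endo-siRNA ordered
  ESC > SSC > GC; ESC/SSC share a correlated miRNA program and ST/MSC
  another (gamma-distributed locus weights with log-normal wobble), so
  correlation clustering pairs SSC with ESC and ST with MSC.
* **Determinism**: every operation takes an explicit seed and uses one
  local RNG stream (`withr::with_seed`); identical inputs give
  byte-identical FASTA/GFF/FASTQ outputs. Seeds are arguments, never
  global state.

What passing tests on these simulations do **not** show: robustness to
overlapping real-world annotations, indels and quality pathologies, PCR
duplicates, or genomes large enough that 18-mers collide by chance. The
generator is a correctness harness, not a realism benchmark.

## Numerical and scale choices

* Problem sizes: unit tests run on a 30 kb bundle with thousands of
  reads; the end-to-end checks use the full default genome with five
  50k-read libraries, and matcher-vs-oracle sweeps use 20 random
  genomes of 30–100 kb with 500 queries each. These sizes make every
  distributional check run at ≥ 3-sigma resolution while keeping a full
  test run in minutes on one core.
* Rounding: percentages round half-up (printed-table convention), not
  half-even.
* Degenerate inputs: empty FASTQ, empty tag sets, empty tracks, all-N
  genomes and zero-read requests all return empty-but-typed results;
  zero clean reads make a mapping percentage undefined and error, as
  does weighting a tag with zero hits.
* `run_pipeline()` is a plain sequential orchestrator; determinism (same
  inputs, same seed, identical report — asserted by test) stands in for
  on-disk caching, which desk-scale runs do not need. The R functions
  are the interface; there is no shell entry point.

## Known limitations

* No mismatch- or gap-tolerant mapping; a single sequencing error
  unmaps a read, which is faithful to perfect-match retention but
  understates mappability relative to aligner-based pipelines.
* No replicate-aware differential expression — the design this package
  addresses has one library per cell type, so signature calling is a
  thresholded fold-change rule, not a statistical test.
* No de novo miRNA discovery, ping-pong analysis, 1U/10A bias, or piRNA
  cluster calling.
* Class trends over an ordered sample series are labelled by Spearman
  sign only; with 3–5 samples no trend test is meaningful and none is
  reported.
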