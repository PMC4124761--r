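# smallRNAsig

Small RNA-seq libraries mix RNA classes with very different biology and
very different quantification needs: ~22 nt miRNAs from hairpin
precursors, fragments of structural RNAs (rRNA/snoRNA/tRNA/scRNA/snRNA),
26–31 nt piRNAs from single-strand, repeat-rich genomic clusters, and
18–23 nt repeat-derived endogenous siRNAs. `smallRNAsig` is an R package
for profiling such libraries end to end — written for people comparing
small RNA programs across cell types (e.g. stem-cell and germ-cell
panels) who need class-aware, multi-mapper-aware quantification rather
than a single expression table.

The pipeline:

1. **Preprocess** — semi-global 3′ adapter trimming, clean-read filtering
   (length 18–40 nt, no N, mean Phred ≥ 20), and collapsing identical
   reads into *tags* (sequence + copy number), with a rejection ledger
   that always balances.
2. **Match** — exhaustive perfect-match lookup of every tag on both
   genome strands. All occurrences are reported: the per-tag hit count
   *#Hits* is the denominator of the multi-mapper weight.
3. **Annotate** — hierarchical classification in the fixed priority
   order **miRNA > rRNA/snoRNA/tRNA/scRNA/snRNA > piRNA > endo-siRNA**,
   by interval overlap (≥ 80% of tag length, strand-aware) against
   per-class tracks; a tag's class is the best class over *all* its hits.
4. **Quantify per class**
   - *miRNA*: mature-arm counts → RPM (`1e6 · count / per-sample miRNA
     total`) → expression calls at RPM ≥ 1 → cell-type signatures
     (fold ≥ 2 vs **each** other sample, zero-guarded as
     `RPM_focal / max(RPM_other, 0.5)`) → average-linkage clustering on
     1 − Pearson correlation of log2 expression.
   - *piRNA*: weighted counts **ω = #Reads / #Hits** per hit, strand-
     resolved binned genome landscapes keyed by 5′ end, and repeat-family
     enrichment between samples (Fisher's exact test on weighted counts,
     BH-corrected).
   - *endo-siRNA*: three-criterion screen (length 18–23 nt, perfect
     genome match, repeat-derived) plus hierarchy exclusion, and weighted
     expression-by-length profiles in tag count per 10 million mapped
     reads.
5. **Report** — Table-style mapping summaries, composition and length
   distributions, and class-trend labels over a declared sample order.

A bundled synthetic-data generator builds toy genomes, annotation tracks
and ground-truthed FASTQ read sets, so the whole pipeline is testable
without any external data. See `vignettes/small-rna-profiling.Rmd` for
the methods and the reasoning behind every default.

## Worked example

```r
library(smallRNAsig)

bundle   <- build_toy_genome(toy_genome_spec(), seed = 101)
profiles <- default_cell_profiles(bundle, seed = 202)
sims     <- lapply(profiles, function(p) simulate_sample(bundle, p, 20000))

ss <- data.frame(sample = names(sims))
ss$reads <- lapply(sims, `[[`, "reads")
report <- run_pipeline(ss, bundle, focal = "SSC")
report
#> RunReport over 5 sample(s)
#>   sample total_clean mapped percentage
#> 1    ESC       19793  19793        100
#> 2    SSC       19777  19777        100
#> 3     GC       19714  19714        100
#> 4     ST       19712  19712        100
#> 5    MSC       19631  19631        100
```

With error-free simulated reads every clean read maps (all reads are
genomic substrings); raw counts fall slightly short of 20,000 because
sub-18 nt background inserts are filtered out. The germ-cell-like
library is piRNA-dominated:

```r
print(report$per_sample$GC$composition, digits = 3)
#>        class reads fraction
#> 1 endo_siRNA   646   0.0358
#> 2      miRNA  3536   0.1961
#> 3      piRNA 11062   0.6133
#> 4       rRNA   988   0.0548
#> ...
```

Clustering pairs the SSC-like with the ESC-like library and the ST-like
with the MSC-like one (shared miRNA programs), and class trends over the
declared order ESC → SSC → GC behave as configured:

```r
report$clustering$merge      # first merges: {ST,MSC}, then {ESC,SSC}
#>      [,1] [,2]
#> [1,]   -4   -5
#> [2,]   -1   -2
#> [3,]   -3    2
#> [4,]    1    3

class_trend_summary(lapply(report$per_sample[c("ESC", "SSC", "GC")],
                           `[[`, "composition"))
#>        class  rho      trend
#> 2      miRNA -1.0  declining
#> 3      piRNA  1.0 increasing
#> ...
```

Signature calling on a matrix with planted focal-specific miRNAs
recovers exactly the planted set (see
`call_signature()` and the planted-recovery tests); the default ESC/SSC
profiles deliberately share a miRNA program, so their mutual signature
is empty.

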