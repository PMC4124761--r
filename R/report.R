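#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#' Defaults follow the package's documented conventions: clean reads are
#' 18–40 nt with mean Phred >= 20 and no N; adapter matches need >= 6 bases
#' at <= 10% mismatches; annotation overlap needs 80% of the tag length;
#' endo-siRNAs are 18–23 nt and >= 50% repeat-overlapped; signatures use a
#' 2-fold rule with a 0.5 RPM zero-guard and the per-sample miRNA total as
#' RPM denominator.
#'
#' @param adapter3,adapter5 adapter sequences for trimming.
#' @param min_overlap,max_mismatch_rate adapter-match parameters.
#' @param min_len,max_len clean-read length window.
#' @param min_mean_quality minimum mean Phred.
#' @param min_overlap_frac annotation overlap fraction.
#' @param pirna_stranded strand rule for piRNA cluster overlap.
#' @param sirna_min_len,sirna_max_len,sirna_repeat_overlap_frac endo-siRNA
#'   screen parameters.
#' @param bin_size piRNA genome-distribution bin size, bp (1 kb suits toy
#'   genomes; use ~100 kb on full genomes).
#' @param fold,eps,expressed_rpm signature-calling parameters.
#' @param mirna_denominator RPM denominator: per-sample miRNA-annotated
#'   total (`"mirna"`, default) or total genome-mapped reads (`"genome"`).
#' @param pirna_floor minimum weighted piRNA total for a sample to appear
#'   in genome-distribution output (samples below it, e.g. MSC-like ones,
#'   are excluded from the landscape report).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(adapter3 = "TGGAATTCTCGGGTGCCAAGGAACTCCAGTCAC",
                            adapter5 = "", min_overlap = 6L,
                            max_mismatch_rate = 0.1,
                            min_len = 18L, max_len = 40L,
                            min_mean_quality = 20,
                            min_overlap_frac = 0.8, pirna_stranded = TRUE,
                            sirna_min_len = 18L, sirna_max_len = 23L,
                            sirna_repeat_overlap_frac = 0.5,
                            bin_size = 1000L, fold = 2, eps = 0.5,
                            expressed_rpm = 1,
                            mirna_denominator = c("mirna", "genome"),
                            pirna_floor = 0) {
  mirna_denominator <- match.arg(mirna_denominator)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Process one sample through preprocess, match and annotate
#'
#' @param reads raw reads (data.frame read_id/seq/qual) or a FASTQ path.
#' @param index a `MatchIndex`.
#' @param ann an `AnnotationSet`.
#' @param repeats repeat GRanges.
#' @param config a [pipeline_config()].
#' @return list: tags, stats, hits, summary (`MappingSummary`), classified,
#'   composition, lengths.
#' @export
process_sample <- function(reads, index, ann, repeats,
                           config = pipeline_config()) {
  if (is.character(reads)) reads <- read_fastq(reads)
  pp <- preprocess_reads(reads, config$adapter3, config$adapter5,
                         config$min_overlap, config$max_mismatch_rate,
                         config$min_len, config$max_len,
                         config$min_mean_quality)
  hits <- match_tags(index, pp$tags)
  summary <- summarize_mapping(pp$tags, hits)
  classified <- classify_tags(pp$tags, hits, ann, repeats,
                              config$min_overlap_frac, config$pirna_stranded,
                              config$sirna_min_len, config$sirna_max_len,
                              config$sirna_repeat_overlap_frac)
  list(tags = pp$tags, stats = pp$stats, hits = hits, summary = summary,
       classified = classified,
       composition = class_composition(classified),
       lengths = length_distribution(classified, config$min_len,
                                     config$max_len))
}

#' Run the whole pipeline over a sample sheet
#'
#' Orchestrates preprocess -> match -> annotate -> class profiles for every
#' sample, then the cross-sample analyses: the mature-miRNA expression
#' matrix with RPM/log2 layers, optional focal-sample signature calling,
#' sample clustering, weighted piRNA genome distributions (samples below
#' `pirna_floor` excluded), pairwise repeat enrichment against the first
#' sample, and the endo-siRNA screen with length profiles. The run is
#' deterministic: the same inputs always produce an identical report.
#'
#' @param samplesheet data.frame with columns `sample` (unique labels) and
#'   either `reads` (list-column / list of read data.frames) or `fastq`
#'   (file paths).
#' @param genome a `GenomeBundle`, DNAStringSet or FASTA path.
#' @param ann an `AnnotationSet` or GFF3 path (defaults to the bundle's own
#'   tracks when `genome` is a bundle).
#' @param repeats repeat GRanges or BED path (defaults to the bundle's).
#' @param config a [pipeline_config()].
#' @param focal optional focal sample for signature calling.
#' @param outdir optional directory; when given, stage TSVs are written.
#' @return a `RunReport` list: per_sample results, mapping_table (Table-1
#'   style), expression (`ExpressionMatrix`), signature, clustering,
#'   pirna_profiles, repeat_enrichment, sirna, config.
#' @export
run_pipeline <- function(samplesheet, genome, ann = NULL, repeats = NULL,
                         config = pipeline_config(), focal = NULL,
                         outdir = NULL) {
  if (anyDuplicated(samplesheet$sample))
    stopf("sample labels must be unique")
  if (inherits(genome, "GenomeBundle")) {
    ann <- ann %||% genome$annotation
    repeats <- repeats %||% genome$repeats
  }
  if (is.character(ann)) ann <- load_annotations(ann)
  if (is.character(repeats)) repeats <- load_repeats(repeats)
  if (is.null(ann)) stopf("an annotation set is required")
  index <- build_index(genome)

  per_sample <- list()
  for (i in seq_len(nrow(samplesheet))) {
    s <- samplesheet$sample[i]
    reads <- if ("reads" %in% names(samplesheet)) samplesheet$reads[[i]]
             else samplesheet$fastq[i]
    per_sample[[s]] <- tryCatch(
      process_sample(reads, index, ann, repeats, config),
      error = function(e) stopf("sample '%s' failed in %s", s,
                                conditionMessage(e)))
  }

  mapping_table <- do.call(rbind, lapply(names(per_sample), function(s) {
    m <- per_sample[[s]]$summary
    data.frame(sample = s, total_clean = m$total_clean, mapped = m$mapped,
               percentage = m$percentage)
  }))

  counts <- lapply(per_sample, function(r)
    count_mature(r$classified, r$hits, ann, config$min_overlap_frac))
  raw <- build_expression_matrix(counts)
  lib <- if (config$mirna_denominator == "mirna") colSums(raw)
         else vapply(per_sample, function(r) as.numeric(r$summary$mapped),
                     numeric(1))
  em <- if (nrow(raw) && all(lib > 0)) rpm_normalize(raw, lib) else NULL
  signature <- if (!is.null(em) && !is.null(focal))
    call_signature(em, focal, fold = config$fold, eps = config$eps,
                   min_rpm = config$expressed_rpm) else NULL
  clustering <- if (!is.null(em) && ncol(raw) >= 2)
    tryCatch(cluster_samples(em, config$expressed_rpm), error = function(e) NULL)
  else NULL

  pirna_profiles <- list()
  pirna_weights <- list()
  for (s in names(per_sample)) {
    r <- per_sample[[s]]
    ptags <- r$classified$tag_id[r$classified$class == "piRNA"]
    w <- weight_tags(r$tags, r$hits, ptags)
    pirna_weights[[s]] <- w
    if (sum(w$omega) > config$pirna_floor)
      pirna_profiles[[s]] <- genome_distribution(
        w, config$bin_size, total_reads = r$summary$mapped)
  }
  enrichment <- NULL
  if (length(pirna_weights) >= 2 && length(repeats)) {
    ref <- names(pirna_weights)[1]
    enrichment <- lapply(setdiff(names(pirna_weights), ref), function(s)
      repeat_enrichment(pirna_weights[[s]], pirna_weights[[ref]], repeats,
                        labels = c(s, ref)))
    names(enrichment) <- setdiff(names(pirna_weights), ref)
  }

  sirna <- lapply(names(per_sample), function(s) {
    r <- per_sample[[s]]
    calls <- screen_endo_sirna(r$tags, r$hits, repeats, r$classified,
                               config$sirna_min_len, config$sirna_max_len,
                               config$sirna_repeat_overlap_frac)
    list(calls = calls,
         profile = sirna_length_profile(calls, r$summary$mapped,
                                        config$sirna_min_len,
                                        config$sirna_max_len))
  })
  names(sirna) <- names(per_sample)

  report <- structure(list(per_sample = per_sample,
                           mapping_table = mapping_table,
                           expression = em, signature = signature,
                           clustering = clustering,
                           pirna_profiles = pirna_profiles,
                           repeat_enrichment = enrichment,
                           sirna = sirna, config = config),
                      class = "RunReport")
  if (!is.null(outdir)) write_run_report(report, outdir)
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport over", nrow(x$mapping_table), "sample(s)\n")
  print(x$mapping_table)
  invisible(x)
}

#' Write the report's stage tables as TSVs
#'
#' @param report a `RunReport`.
#' @param outdir output directory.
#' @return the directory, invisibly.
#' @export
write_run_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) write.table(d, file.path(outdir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(report$mapping_table, "mapping_summary.tsv")
  for (s in names(report$per_sample)) {
    r <- report$per_sample[[s]]
    tsv(r$classified, paste0(s, ".classified.tsv"))
    tsv(r$composition, paste0(s, ".composition.tsv"))
    tsv(r$lengths, paste0(s, ".lengths.tsv"))
  }
  if (!is.null(report$expression)) {
    m <- report$expression$rpm
    tsv(data.frame(feature = rownames(m), m, check.names = FALSE),
        "mirna_rpm.tsv")
  }
  if (!is.null(report$signature)) tsv(report$signature, "signature.tsv")
  for (s in names(report$pirna_profiles))
    tsv(report$pirna_profiles[[s]], paste0(s, ".pirna_bins.tsv"))
  for (s in names(report$sirna))
    tsv(report$sirna[[s]]$profile, paste0(s, ".sirna_lengths.tsv"))
  invisible(outdir)
}

#' Label per-class composition trends over an ordered sample series
#'
#' Given class compositions for samples in a user-declared (e.g.
#' developmental) order, labels each class's trend by the sign of the
#' Spearman correlation between its fraction and the order index:
#' `increasing`, `declining`, or `flat`. Descriptive only — with 3–5
#' ordered samples no test is meaningful.
#'
#' @param compositions named list of composition tables from
#'   [class_composition()], in the declared order.
#' @return data.frame: class, rho, trend.
#' @export
class_trend_summary <- function(compositions) {
  if (length(compositions) < 2)
    stopf("need at least 2 ordered samples for a trend")
  classes <- sort(unique(unlist(lapply(compositions, `[[`, "class"))))
  frac <- vapply(compositions, function(d) {
    setNames(d$fraction, d$class)[classes]
  }, numeric(length(classes)))
  frac <- matrix(frac, nrow = length(classes),
                 dimnames = list(classes, names(compositions)))
  frac[is.na(frac)] <- 0
  idx <- seq_len(ncol(frac))
  rho <- apply(frac, 1, function(v) {
    if (stats::sd(v) == 0) return(NA_real_)
    suppressWarnings(cor(v, idx, method = "spearman"))
  })
  trend <- ifelse(is.na(rho) | rho == 0, "flat",
                  ifelse(rho > 0, "increasing", "declining"))
  data.frame(class = classes, rho = unname(rho), trend = unname(trend),
             row.names = NULL)
}
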