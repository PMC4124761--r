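#' Read a FASTQ file into a data frame
#'
#' @param path FASTQ path, optionally gzipped.
#' @return data.frame with columns read_id, seq, qual.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stopf("FASTQ file not found: %s", path)
  qs <- tryCatch(suppressWarnings(
                   Biostrings::readQualityScaledDNAStringSet(path)),
                 error = function(e)
                   stopf("failed to parse FASTQ '%s': %s", path,
                         conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(qs))
  data.frame(read_id = ids, seq = as.character(qs),
             qual = as.character(Biostrings::quality(qs)),
             row.names = NULL)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with read_id, seq, qual.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(as.character(reads$seq),
                                         reads$read_id))
  qs <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    x, Biostrings::PhredQuality(as.character(reads$qual))))
  Biostrings::writeQualityScaledXStringSet(qs, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

# One combined GRanges with GFF3 `type` per class track, for export.
bundle_annotation_gr <- function(ann) {
  pieces <- list()
  add <- function(gr, type, parent = NULL) {
    if (length(gr) == 0L) return()
    out <- GenomicRanges::granges(gr)
    S4Vectors::mcols(out)$type <- type
    S4Vectors::mcols(out)$ID <- S4Vectors::mcols(gr)$locus_id
    S4Vectors::mcols(out)$Parent <- if (is.null(parent))
      rep(NA_character_, length(gr)) else parent
    pieces[[length(pieces) + 1L]] <<- out
  }
  add(ann$mirna_hairpin, "miRNA_hairpin")
  add(ann$mirna_mature, "miRNA_mature", S4Vectors::mcols(ann$mirna_mature)$parent)
  for (cls in names(ann$structural)) add(ann$structural[[cls]], cls)
  add(ann$pirna, "piRNA_cluster")
  if (length(pieces) == 0L) return(GenomicRanges::GRanges())
  do.call(c, pieces)
}

#' Write a genome bundle to disk
#'
#' Emits the genome as FASTA, all class tracks as one GFF3 (class in the
#' `type` column, locus id in the `ID` attribute, mature arms carrying a
#' `Parent` link to their hairpin), and the repeat track as BED6 with the
#' family label in the name column.
#'
#' @param bundle a `GenomeBundle`.
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths.
#' @export
write_genome_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "annotation.gff3")
  bed <- file.path(dir, "repeats.bed")
  Biostrings::writeXStringSet(bundle$genome, fa)
  gr <- bundle_annotation_gr(bundle$annotation)
  rtracklayer::export(gr, gff, format = "gff3")
  reps <- bundle$repeats
  if (length(reps)) {
    out <- GenomicRanges::granges(reps)
    S4Vectors::mcols(out)$name <- S4Vectors::mcols(reps)$family
    S4Vectors::mcols(out)$score <- 0L
    rtracklayer::export(out, bed, format = "bed")
  } else {
    file.create(bed)
  }
  c(genome = fa, annotation = gff, repeats = bed)
}

#' Write a truth table as TSV
#' @param truth truth table data.frame from [simulate_sample()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tag set as FASTA
#'
#' Headers follow the conventional collapsed-read form `t<rank>_x<count>`.
#'
#' @param tags TagSet data.frame (tag_id, seq, count).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tags_fasta <- function(tags, path) {
  x <- Biostrings::DNAStringSet(setNames(as.character(tags$seq), tags$tag_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a collapsed-tag FASTA
#' @param path FASTA of tags with `t<rank>_x<count>` headers.
#' @return TagSet data.frame (tag_id, seq, count).
#' @export
read_tags_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  cnt <- suppressWarnings(as.integer(sub("^.*_x", "", names(x))))
  if (anyNA(cnt)) stopf("tag FASTA headers must end in _x<count>: %s", path)
  data.frame(tag_id = names(x), seq = as.character(x), count = cnt,
             row.names = NULL)
}
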