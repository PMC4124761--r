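#' Build an exact-match index over a genome
#'
#' Prepares both strands of the genome for exhaustive perfect-match lookup
#' of 18–40 nt tags. Matching is exact and exhaustive by contract: every
#' occurrence on either strand is reported, and positions containing N never
#' match. Internally the forward sequence and its reverse complement are
#' held as pattern-dictionary subjects.
#'
#' @param genome a `GenomeBundle`, a named [Biostrings::DNAStringSet], or a
#'   FASTA path.
#' @return a `MatchIndex`.
#' @export
build_index <- function(genome) {
  if (inherits(genome, "GenomeBundle")) genome <- genome$genome
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet"))
    stopf("genome must be a GenomeBundle, DNAStringSet or FASTA path")
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L)
    stopf("empty genome: cannot build a match index")
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stopf("genome chromosomes must carry unique names")
  names(genome) <- sub("\\s.*$", "", names(genome))
  structure(list(fwd = genome,
                 rev = Biostrings::reverseComplement(genome),
                 chrom_lens = setNames(Biostrings::width(genome),
                                       names(genome))),
            class = "MatchIndex")
}

#' Find all perfect-match genomic hits of each tag
#'
#' Reports every occurrence of every tag on both strands (multi-mapping is
#' preserved in full: the per-tag hit count `n_hits` is the denominator of
#' the weighted read count used for piRNA/endo-siRNA quantification). A tag
#' equal to its own reverse complement yields both a plus- and a
#' minus-strand hit at the same locus. Coordinates are 0-based, half-open.
#' Unmapped tags are simply absent from the result.
#'
#' @param index a `MatchIndex` from [build_index()].
#' @param tags TagSet data.frame (tag_id, seq, count) or character vector.
#' @return data.frame of hits: tag_id, chrom, start (0-based), end
#'   (half-open), strand, n_hits.
#' @export
match_tags <- function(index, tags) {
  stopifnot(inherits(index, "MatchIndex"))
  if (is.character(tags))
    tags <- data.frame(tag_id = paste0("t", seq_along(tags)), seq = tags,
                       count = 1L)
  empty <- data.frame(tag_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_hits = integer(0))
  if (nrow(tags) == 0L) return(empty)
  ok <- !grepl("[^ACGT]", tags$seq)
  tags <- tags[ok, , drop = FALSE]
  if (nrow(tags) == 0L) return(empty)

  parts <- list()
  for (w in sort(unique(nchar(tags$seq)))) {
    grp <- tags[nchar(tags$seq) == w, , drop = FALSE]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(grp$seq))
    for (chrom in names(index$fwd)) {
      L <- index$chrom_lens[[chrom]]
      if (L < w) next
      fs <- Biostrings::startIndex(
        Biostrings::matchPDict(pd, index$fwd[[chrom]]))
      rs <- Biostrings::startIndex(
        Biostrings::matchPDict(pd, index$rev[[chrom]]))
      nf <- lengths(fs); nr <- lengths(rs)
      if (sum(nf) + sum(nr) == 0L) next
      parts[[length(parts) + 1L]] <- data.frame(
        tag_id = c(rep(grp$tag_id, nf), rep(grp$tag_id, nr)),
        chrom = chrom,
        # minus-strand starts found on the reverse complement map back to
        # forward coordinates: rc position s1..e1 -> forward [L-e1, L-s1+1)
        start = c(unlist(fs, use.names = FALSE) - 1L,
                  L - (unlist(rs, use.names = FALSE) + w - 1L)),
        end = NA_integer_,
        strand = c(rep("+", sum(nf)), rep("-", sum(nr))),
        stringsAsFactors = FALSE)
      parts[[length(parts)]]$end <- parts[[length(parts)]]$start + w
    }
  }
  if (length(parts) == 0L) return(empty)
  hits <- do.call(rbind, parts)
  # canonical order: by tag, chrom, start, strand — independent of scan order
  hits <- hits[order(match(hits$tag_id, tags$tag_id), hits$chrom, hits$start,
                     hits$strand, method = "radix"), , drop = FALSE]
  rownames(hits) <- NULL
  nh <- table(hits$tag_id)
  hits$n_hits <- as.integer(nh[hits$tag_id])
  hits
}

#' Per-tag hit counts
#' @param hits hit data.frame from [match_tags()].
#' @return named integer vector, tag_id -> n_hits.
#' @export
hit_counts <- function(hits) {
  u <- unique(hits[, c("tag_id", "n_hits")])
  setNames(u$n_hits, u$tag_id)
}

#' Construct a mapping summary from read counts
#'
#' The summary row of a sequencing run: total clean reads, reads whose tag
#' has at least one perfect genome hit, and the mapping percentage rounded
#' half-up to two decimals (the convention of printed sequencing summary
#' tables).
#'
#' @param total_clean total clean reads.
#' @param mapped clean reads with a mapped tag.
#' @return a `MappingSummary` (list: total_clean, mapped, percentage).
#' @export
mapping_summary <- function(total_clean, mapped) {
  if (total_clean == 0) stopf("mapping percentage undefined: no clean reads")
  if (mapped < 0 || mapped > total_clean)
    stopf("mapped must lie in [0, total_clean]")
  structure(list(total_clean = total_clean, mapped = mapped,
                 percentage = round_half_up(100 * mapped / total_clean, 2)),
            class = "MappingSummary")
}

#' Summarise genome mapping of a tag set
#'
#' @param tags TagSet data.frame (tag_id, seq, count).
#' @param hits hit data.frame from [match_tags()] for those tags.
#' @return a `MappingSummary`.
#' @export
summarize_mapping <- function(tags, hits) {
  mapped_tags <- unique(hits$tag_id)
  if (!all(mapped_tags %in% tags$tag_id))
    stopf("hits contain tag ids absent from the tag set")
  mapping_summary(sum(tags$count),
                  sum(tags$count[tags$tag_id %in% mapped_tags]))
}

#' @export
print.MappingSummary <- function(x, ...) {
  cat(sprintf("MappingSummary: %s clean, %s mapped (%.2f%%)\n",
              format(x$total_clean, big.mark = ","),
              format(x$mapped, big.mark = ","), x$percentage))
  invisible(x)
}
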