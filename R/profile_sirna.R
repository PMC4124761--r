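#' Screen tags for endo-siRNA candidates
#'
#' Applies the three endo-siRNA screening criteria — (1) length within the
#' endo-siRNA window (18–23 nt), (2) at least one perfect genome match,
#' (3) repeat-derived (some hit overlapping a repeat interval over at least
#' `repeat_overlap_frac` of the tag length) — plus the annotation-hierarchy
#' exclusion: a tag already claimed by miRNA, a structural class or piRNA
#' cannot also be an endo-siRNA. Each criterion is reported separately so
#' the screen is auditable; the overall call is their conjunction.
#'
#' @param tags TagSet data.frame (tag_id, seq, count).
#' @param hits hit table from [match_tags()].
#' @param repeats repeat GRanges (`family`, `locus_id` columns).
#' @param classified optional classification table from [classify_tags()];
#'   when given, tags classified to a higher-priority class fail the
#'   hierarchy exclusion.
#' @param min_len,max_len endo-siRNA length window, inclusive.
#' @param repeat_overlap_frac minimum repeat overlap fraction of tag length.
#' @return data.frame, one row per tag: tag_id, length, count, n_hits,
#'   omega, the per-criterion logicals (len_ok, mapped, repeat_derived,
#'   no_higher_class) and `pass`.
#' @export
screen_endo_sirna <- function(tags, hits, repeats, classified = NULL,
                              min_len = 18L, max_len = 23L,
                              repeat_overlap_frac = 0.5) {
  n <- nrow(tags)
  len <- nchar(tags$seq)
  nh <- hit_counts(hits)
  n_hits <- ifelse(tags$tag_id %in% names(nh), nh[tags$tag_id], 0L)
  mapped <- n_hits > 0L
  len_ok <- len >= min_len & len <= max_len

  repeat_derived <- rep(FALSE, n)
  if (length(repeats) && nrow(hits)) {
    h <- hits[hits$tag_id %in% tags$tag_id, , drop = FALSE]
    hgr <- hits_to_granges(h)
    ov <- GenomicRanges::findOverlaps(hgr, repeats, ignore.strand = TRUE)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      w <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(hgr)[qh], GenomicRanges::ranges(repeats)[sh]))
      tid <- S4Vectors::mcols(hgr)$tag_id[qh]
      tlen <- setNames(len, tags$tag_id)
      good <- unique(tid[w >= repeat_overlap_frac * tlen[tid]])
      repeat_derived <- tags$tag_id %in% good
    }
  }

  no_higher <- rep(TRUE, n)
  if (!is.null(classified)) {
    higher <- classified$tag_id[!classified$class %in%
                                  c("endo_siRNA", "unannotated")]
    no_higher <- !tags$tag_id %in% higher
  }

  data.frame(tag_id = tags$tag_id, length = len, count = tags$count,
             n_hits = as.integer(n_hits),
             omega = ifelse(mapped, tags$count / n_hits, NA_real_),
             len_ok = len_ok, mapped = mapped,
             repeat_derived = repeat_derived, no_higher_class = no_higher,
             pass = len_ok & mapped & repeat_derived & no_higher)
}

#' Weighted endo-siRNA expression by read length
#'
#' Sums the per-tag weighted count (count/n_hits, one term per passing tag)
#' at each length of the endo-siRNA window and scales to tag count per 10
#' million mapped reads — the unit conventionally printed for endo-siRNA
#' length profiles.
#'
#' @param calls screen table from [screen_endo_sirna()].
#' @param total_mapped_reads per-sample scaling denominator (total
#'   genome-mapped reads); must be > 0.
#' @param min_len,max_len length window to report.
#' @return data.frame: length, weighted_count, tags_per_10M.
#' @export
sirna_length_profile <- function(calls, total_mapped_reads,
                                 min_len = 18L, max_len = 23L) {
  if (total_mapped_reads <= 0)
    stopf("total_mapped_reads must be positive")
  ok <- calls[calls$pass, , drop = FALSE]
  lens <- min_len:max_len
  w <- vapply(lens, function(L) sum(ok$omega[ok$length == L]), numeric(1))
  data.frame(length = lens, weighted_count = w,
             tags_per_10M = 1e7 * w / total_mapped_reads)
}
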