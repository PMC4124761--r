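#' Assemble per-class annotation tracks
#'
#' Bundles the interval tracks used for hierarchical classification. The
#' priority order is fixed: miRNA first, then the structural tier
#' (rRNA/snoRNA/tRNA/scRNA/snRNA), then piRNA clusters; endo-siRNA is
#' assigned by rule afterwards, never by track. Mature miRNA arms must nest
#' inside their hairpins, and every piRNA cluster must carry a definite
#' strand (piRNA clusters are single-strand annotations).
#'
#' @param mirna_hairpin GRanges of miRNA hairpins (`locus_id` column).
#' @param mirna_mature GRanges of mature arms (`locus_id`, `parent`).
#' @param structural named list of GRanges, names among
#'   rRNA/snoRNA/tRNA/scRNA/snRNA; absent classes simply never match.
#' @param pirna GRanges of piRNA clusters (stranded).
#' @return an `AnnotationSet`.
#' @export
annotation_set <- function(mirna_hairpin = GenomicRanges::GRanges(),
                           mirna_mature = GenomicRanges::GRanges(),
                           structural = list(),
                           pirna = GenomicRanges::GRanges()) {
  bad <- setdiff(names(structural), structural_classes())
  if (length(bad)) stopf("unknown structural class: %s", paste(bad, collapse = ", "))
  for (g in c(list(mirna_hairpin, mirna_mature, pirna), structural)) {
    if (length(g) && is.null(S4Vectors::mcols(g)$locus_id))
      stopf("every annotation track needs a locus_id column")
    sl <- GenomeInfoDb::seqlengths(g)
    if (length(g) && any(!is.na(sl))) {
      lim <- sl[as.character(GenomicRanges::seqnames(g))]
      if (any(!is.na(lim) & (GenomicRanges::start(g) < 1 |
                             GenomicRanges::end(g) > lim)))
        stopf("annotation interval outside chromosome bounds")
    }
  }
  if (length(mirna_mature)) {
    within <- IRanges::overlapsAny(mirna_mature, mirna_hairpin,
                                   type = "within", ignore.strand = TRUE)
    if (!all(within))
      stopf("mature miRNA intervals must nest inside hairpin intervals")
  }
  if (length(pirna) && any(as.character(GenomicRanges::strand(pirna)) == "*"))
    stopf("piRNA clusters must carry a definite strand")
  structure(list(mirna_hairpin = mirna_hairpin, mirna_mature = mirna_mature,
                 structural = structural, pirna = pirna),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat("AnnotationSet (priority miRNA > rRNA/snoRNA/tRNA/scRNA/snRNA",
      "> piRNA > endo-siRNA):\n")
  cat("  miRNA:", length(x$mirna_hairpin), "hairpins,",
      length(x$mirna_mature), "matures\n")
  for (cls in names(x$structural))
    cat(" ", cls, ":", length(x$structural[[cls]]), "loci\n")
  cat("  piRNA:", length(x$pirna), "clusters\n")
  invisible(x)
}

#' Load annotation tracks from GFF3
#'
#' Reads a GFF3 in which the `type` column names the class
#' (`miRNA_hairpin`, `miRNA_mature`, `rRNA`, `snoRNA`, `tRNA`, `scRNA`,
#' `snRNA`, `piRNA_cluster`) and the `ID` attribute holds the locus id.
#' GFF3's 1-based inclusive coordinates become the package's internal
#' convention automatically (GRanges are 1-based inclusive; hit coordinates
#' are converted at the classification boundary).
#'
#' @param gff path to the GFF3 file.
#' @return an `AnnotationSet`.
#' @export
load_annotations <- function(gff) {
  gr <- tryCatch(rtracklayer::import(gff, format = "gff3"),
                 error = function(e)
                   stopf("failed to parse GFF3 '%s': %s", gff,
                         conditionMessage(e)))
  types <- as.character(S4Vectors::mcols(gr)$type)
  known <- c("miRNA_hairpin", "miRNA_mature", structural_classes(),
             "piRNA_cluster")
  bad <- setdiff(unique(types), known)
  if (length(bad))
    stopf("unknown annotation class in '%s': %s", gff,
          paste(bad, collapse = ", "))
  take <- function(tt) {
    g <- gr[types == tt]
    out <- GenomicRanges::granges(g)
    S4Vectors::mcols(out)$locus_id <- as.character(S4Vectors::mcols(g)$ID)
    if (tt == "miRNA_mature") {
      par <- S4Vectors::mcols(g)$Parent
      S4Vectors::mcols(out)$parent <-
        vapply(as.list(par), function(p) if (length(p)) as.character(p[1])
               else NA_character_, character(1))
    }
    out
  }
  annotation_set(
    mirna_hairpin = take("miRNA_hairpin"),
    mirna_mature = take("miRNA_mature"),
    structural = setNames(lapply(structural_classes(), take),
                          structural_classes()),
    pirna = take("piRNA_cluster"))
}

#' Load a repeat track from BED6
#'
#' The BED name column carries the repeat family label (e.g. ERV1, LINE).
#'
#' @param bed path to the BED file.
#' @return GRanges with `family` and `locus_id` columns.
#' @export
load_repeats <- function(bed) {
  if (file.info(bed)$size == 0)
    return(GenomicRanges::GRanges(family = character(0),
                                  locus_id = character(0)))
  gr <- tryCatch(rtracklayer::import(bed, format = "bed"),
                 error = function(e)
                   stopf("failed to parse BED '%s': %s", bed,
                         conditionMessage(e)))
  out <- GenomicRanges::granges(gr)
  fam <- as.character(S4Vectors::mcols(gr)$name)
  S4Vectors::mcols(out)$family <- fam
  S4Vectors::mcols(out)$locus_id <- paste0("rep_", fam, "_", seq_along(gr))
  out
}

# Hits (0-based half-open data.frame) as a 1-based GRanges carrying tag ids.
hits_to_granges <- function(hits) {
  GenomicRanges::GRanges(hits$chrom,
                         IRanges::IRanges(hits$start + 1L, hits$end),
                         strand = hits$strand,
                         tag_id = hits$tag_id, hit_row = seq_len(nrow(hits)))
}

# Combined GRanges for one priority tier with class + class_rank columns.
tier_track <- function(ann, tier) {
  if (tier == "miRNA") {
    pieces <- list()
    # mature arms rank above hairpins: on equal overlap the more specific
    # feature wins, so the assigned locus is the mature id when possible
    sub <- list(list(ann$mirna_mature, 1L), list(ann$mirna_hairpin, 2L))
    for (p in sub) {
      g <- p[[1]]
      if (!length(g)) next
      out <- GenomicRanges::granges(g)
      S4Vectors::mcols(out) <-
        S4Vectors::DataFrame(locus_id = S4Vectors::mcols(g)$locus_id,
                             class = "miRNA", class_rank = p[[2]])
      pieces[[length(pieces) + 1L]] <- out
    }
    if (!length(pieces)) return(NULL)
    return(suppressWarnings(do.call(c, pieces)))
  }
  if (tier == "structural") {
    pieces <- list()
    for (k in seq_along(structural_classes())) {
      cls <- structural_classes()[k]
      g <- ann$structural[[cls]]
      if (is.null(g) || !length(g)) next
      out <- GenomicRanges::granges(g)
      S4Vectors::mcols(out) <-
        S4Vectors::DataFrame(locus_id = S4Vectors::mcols(g)$locus_id,
                             class = cls, class_rank = k)
      pieces[[length(pieces) + 1L]] <- out
    }
    if (!length(pieces)) return(NULL)
    return(suppressWarnings(do.call(c, pieces)))
  }
  g <- ann$pirna
  if (!length(g)) return(NULL)
  out <- GenomicRanges::granges(g)
  S4Vectors::mcols(out) <-
    S4Vectors::DataFrame(locus_id = S4Vectors::mcols(g)$locus_id,
                         class = "piRNA", class_rank = 1L)
  out
}

#' Classify tags by the hierarchical annotation order
#'
#' Each mapped tag is assigned the highest-priority class overlapped by ANY
#' of its genomic hits (the multi-mapper rule mirrors read-level database
#' annotation, where any hit classifies the read). An overlap counts when it
#' covers at least `min_overlap_frac` of the tag length and satisfies the
#' strand rule: miRNA and structural classes require same-strand overlap;
#' piRNA overlap may optionally be strand-agnostic. Ties within a tier are
#' broken by largest overlap, then class order, then lexicographic locus id
#' — so the result never depends on input order. Tags claimed by no track
#' are tested against the endo-siRNA rule (length 18–23 nt, perfect genome
#' match, repeat-derived); the rest are `unannotated`.
#'
#' @param tags TagSet data.frame (tag_id, seq, count).
#' @param hits hit data.frame from [match_tags()].
#' @param ann an `AnnotationSet`.
#' @param repeats optional repeat GRanges (family, locus_id) for the
#'   endo-siRNA rule; NULL disables endo-siRNA assignment.
#' @param min_overlap_frac minimum overlap as a fraction of tag length.
#' @param pirna_stranded if TRUE (default) piRNA overlap must be
#'   same-strand; FALSE allows either strand.
#' @param sirna_min_len,sirna_max_len endo-siRNA length window (nt).
#' @param sirna_repeat_overlap_frac minimum repeat overlap fraction for the
#'   repeat-derived criterion.
#' @return data.frame, one row per mapped tag: tag_id, seq, count, length,
#'   n_hits, class, locus_id, chrom, start, strand (the assigning hit;
#'   NA for unannotated).
#' @export
classify_tags <- function(tags, hits, ann, repeats = NULL,
                          min_overlap_frac = 0.8, pirna_stranded = TRUE,
                          sirna_min_len = 18L, sirna_max_len = 23L,
                          sirna_repeat_overlap_frac = 0.5) {
  stopifnot(inherits(ann, "AnnotationSet"))
  mapped <- tags[tags$tag_id %in% hits$tag_id, , drop = FALSE]
  out <- data.frame(tag_id = mapped$tag_id, seq = mapped$seq,
                    count = mapped$count, length = nchar(mapped$seq),
                    n_hits = as.integer(hit_counts(hits)[mapped$tag_id]),
                    class = "unannotated", locus_id = NA_character_,
                    chrom = NA_character_, start = NA_integer_,
                    strand = NA_character_)
  rownames(out) <- out$tag_id
  if (nrow(out) == 0L) return(out)
  hgr <- hits_to_granges(hits)
  taglen <- setNames(out$length, out$tag_id)

  assign_tier <- function(track, ignore_strand) {
    unassigned <- out$tag_id[out$class == "unannotated"]
    if (is.null(track) || !length(unassigned)) return()
    sel <- which(hits$tag_id %in% unassigned)
    if (!length(sel)) return()
    h <- hgr[sel]
    ov <- GenomicRanges::findOverlaps(h, track, ignore.strand = ignore_strand)
    if (!length(ov)) return()
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(h)[qh], GenomicRanges::ranges(track)[sh]))
    tid <- S4Vectors::mcols(h)$tag_id[qh]
    keep <- w >= min_overlap_frac * taglen[tid]
    if (!any(keep)) return()
    cand <- data.frame(tag_id = tid[keep],
                       locus_id = S4Vectors::mcols(track)$locus_id[sh[keep]],
                       class = S4Vectors::mcols(track)$class[sh[keep]],
                       class_rank = S4Vectors::mcols(track)$class_rank[sh[keep]],
                       overlap = w[keep],
                       hit_row = S4Vectors::mcols(h)$hit_row[qh[keep]])
    cand <- cand[order(cand$tag_id, -cand$overlap, cand$class_rank,
                       cand$locus_id, method = "radix"), , drop = FALSE]
    best <- cand[!duplicated(cand$tag_id), , drop = FALSE]
    hr <- hits[best$hit_row, , drop = FALSE]
    out[best$tag_id, c("class", "locus_id", "chrom", "start", "strand")] <<-
      data.frame(best$class, best$locus_id, hr$chrom, hr$start, hr$strand)
  }

  assign_tier(tier_track(ann, "miRNA"), ignore_strand = FALSE)
  assign_tier(tier_track(ann, "structural"), ignore_strand = FALSE)
  assign_tier(tier_track(ann, "piRNA"), ignore_strand = !pirna_stranded)

  if (!is.null(repeats) && length(repeats)) {
    unassigned <- out$tag_id[out$class == "unannotated" &
                               out$length >= sirna_min_len &
                               out$length <= sirna_max_len]
    if (length(unassigned)) {
      sel <- which(hits$tag_id %in% unassigned)
      h <- hgr[sel]
      ov <- GenomicRanges::findOverlaps(h, repeats, ignore.strand = TRUE)
      if (length(ov)) {
        qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
        w <- GenomicRanges::width(IRanges::pintersect(
          GenomicRanges::ranges(h)[qh], GenomicRanges::ranges(repeats)[sh]))
        tid <- S4Vectors::mcols(h)$tag_id[qh]
        keep <- w >= sirna_repeat_overlap_frac * taglen[tid]
        if (any(keep)) {
          cand <- data.frame(tag_id = tid[keep],
                             locus_id = S4Vectors::mcols(repeats)$locus_id[sh[keep]],
                             overlap = w[keep],
                             hit_row = S4Vectors::mcols(h)$hit_row[qh[keep]])
          cand <- cand[order(cand$tag_id, -cand$overlap, cand$locus_id,
                             method = "radix"), , drop = FALSE]
          best <- cand[!duplicated(cand$tag_id), , drop = FALSE]
          hr <- hits[best$hit_row, , drop = FALSE]
          out[best$tag_id,
              c("class", "locus_id", "chrom", "start", "strand")] <-
            data.frame("endo_siRNA", best$locus_id, hr$chrom, hr$start,
                       hr$strand)
        }
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Per-class read composition
#'
#' Read-weighted class composition of a sample: absolute read counts per
#' class and fractions over annotated reads (the unannotated count is
#' reported alongside, not inside the fractions).
#'
#' @param classified classification data.frame from [classify_tags()].
#' @return data.frame (class, reads, fraction) with attribute
#'   `unannotated_reads`.
#' @export
class_composition <- function(classified) {
  ann <- classified[classified$class != "unannotated", , drop = FALSE]
  cls <- sort(unique(ann$class))
  reads <- vapply(cls, function(k) sum(ann$count[ann$class == k]), numeric(1))
  out <- data.frame(class = cls, reads = as.numeric(reads),
                    fraction = if (sum(reads) > 0) reads / sum(reads)
                               else rep(NA_real_, length(reads)))
  rownames(out) <- NULL
  attr(out, "unannotated_reads") <-
    sum(classified$count[classified$class == "unannotated"])
  out
}

#' Read-length distribution
#'
#' Read totals per tag length over the retained window, optionally weighted
#' (e.g. by the multi-hit weight count/n_hits instead of the raw count).
#'
#' @param tags data.frame with `seq` and `count` columns (TagSet or
#'   classification table).
#' @param min_len,max_len length window to tabulate, inclusive.
#' @param weights optional per-tag weights replacing `count`.
#' @return data.frame (length, reads, density); densities sum to 1 when any
#'   reads fall in the window.
#' @export
length_distribution <- function(tags, min_len = 18L, max_len = 40L,
                                weights = NULL) {
  lens <- min_len:max_len
  w <- weights %||% tags$count
  lt <- nchar(tags$seq)
  reads <- vapply(lens, function(L) sum(w[lt == L]), numeric(1))
  data.frame(length = lens, reads = reads,
             density = if (sum(reads) > 0) reads / sum(reads)
                       else rep(0, length(lens)))
}
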