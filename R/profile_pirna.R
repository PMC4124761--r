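#' Weight multi-mapping tags across their hits
#'
#' Implements the weighted read count for multi-mappers: a tag with #Reads
#' copies and #Hits genomic occurrences contributes omega = #Reads/#Hits at
#' each of its hits, so its total contribution is exactly its read count
#' wherever it maps. Uniquely mapping tags reduce to their raw counts.
#'
#' @param tags TagSet data.frame (tag_id, seq, count).
#' @param hits hit table from [match_tags()].
#' @param tag_ids tags to weight (default: all tags present in `hits`);
#'   requesting a tag with no hits is an error — weighting is only defined
#'   for mapped tags.
#' @return data.frame of weighted hits: tag_id, chrom, start, end, strand,
#'   n_hits, omega.
#' @export
weight_tags <- function(tags, hits, tag_ids = NULL) {
  tag_ids <- tag_ids %||% intersect(tags$tag_id, unique(hits$tag_id))
  missing <- setdiff(tag_ids, hits$tag_id)
  if (length(missing))
    stopf("cannot weight tags with zero hits: %s",
          paste(head(missing, 3), collapse = ", "))
  h <- hits[hits$tag_id %in% tag_ids, , drop = FALSE]
  cnt <- setNames(tags$count, tags$tag_id)
  h$omega <- as.numeric(cnt[h$tag_id]) / h$n_hits
  rownames(h) <- NULL
  h
}

#' Strand-resolved binned genome distribution of weighted signal
#'
#' Each weighted hit contributes its omega to the genomic bin containing
#' its 5' end (strand-aware: the start for plus-strand hits, the last base
#' for minus-strand hits), keyed separately by strand. Weighted totals are
#' also expressed as weighted RPM over `total_reads`. Summed over all bins
#' and both strands the raw weights equal the total weighted signal
#' exactly, and re-binning to a coarser bin size is sum-consistent.
#'
#' @param whits weighted hits from [weight_tags()].
#' @param bin_size bin width in bp (>= 1).
#' @param total_reads RPM denominator; defaults to the summed omega of the
#'   input (so RPMs sum to 1e6).
#' @return a `StrandBinProfile` data.frame: chrom, bin_start, strand,
#'   weight, weighted_rpm; attributes `bin_size` and `total_reads`.
#' @export
genome_distribution <- function(whits, bin_size, total_reads = NULL) {
  if (bin_size < 1) stopf("bin_size must be >= 1")
  if (nrow(whits) == 0L) {
    out <- data.frame(chrom = character(0), bin_start = integer(0),
                      strand = character(0), weight = numeric(0),
                      weighted_rpm = numeric(0))
  } else {
    pos5 <- ifelse(whits$strand == "+", whits$start, whits$end - 1L)
    bin <- (pos5 %/% bin_size) * bin_size
    key <- paste(whits$chrom, bin, whits$strand, sep = "\r")
    agg <- tapply(whits$omega, key, sum)
    parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
    out <- data.frame(chrom = parts[, 1],
                      bin_start = as.integer(parts[, 2]),
                      strand = parts[, 3], weight = as.numeric(agg))
    out <- out[order(out$chrom, out$bin_start, out$strand,
                     method = "radix"), , drop = FALSE]
    total_reads <- total_reads %||% sum(whits$omega)
    out$weighted_rpm <- 1e6 * out$weight / total_reads
    rownames(out) <- NULL
  }
  attr(out, "bin_size") <- bin_size
  attr(out, "total_reads") <- total_reads
  class(out) <- c("StrandBinProfile", "data.frame")
  out
}

#' Export a strand-resolved profile as bedGraph
#'
#' One bedGraph file per strand, values in weighted RPM.
#'
#' @param profile a `StrandBinProfile`.
#' @param prefix output path prefix; files `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph` are written.
#' @return named character vector of written paths.
#' @export
write_bedgraph <- function(profile, prefix) {
  bs <- attr(profile, "bin_size")
  paths <- c(plus = paste0(prefix, ".plus.bedgraph"),
             minus = paste0(prefix, ".minus.bedgraph"))
  for (st in c("plus", "minus")) {
    d <- profile[profile$strand == ifelse(st == "plus", "+", "-"), ,
                 drop = FALSE]
    write.table(data.frame(d$chrom, d$bin_start, d$bin_start + bs,
                           d$weighted_rpm),
                paths[[st]], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Repeat-family enrichment of weighted signal between two samples
#'
#' For each repeat family, the weighted signal falling inside the family's
#' intervals (strand-agnostic, each hit counted once per family) is
#' compared between two samples with Fisher's exact test on the 2x2 table
#' of (in-family, out-of-family) weighted counts rounded to integers,
#' followed by Benjamini-Hochberg correction across families.
#'
#' @param whits_a,whits_b weighted hits from [weight_tags()] for the two
#'   samples.
#' @param repeats repeat GRanges with a `family` column.
#' @param labels sample labels for the output columns.
#' @return data.frame: family, weight/fraction per sample, odds_ratio,
#'   p_value, q_value, enriched (q < 0.05).
#' @export
repeat_enrichment <- function(whits_a, whits_b, repeats,
                              labels = c("A", "B")) {
  fams <- sort(unique(as.character(S4Vectors::mcols(repeats)$family)))
  if (!length(fams) || length(repeats) == 0L)
    return(data.frame(family = character(0)))
  fam_weight <- function(wh) {
    tot <- sum(wh$omega)
    if (nrow(wh) == 0L)
      return(list(tot = 0, w = setNames(rep(0, length(fams)), fams)))
    gr <- GenomicRanges::GRanges(wh$chrom,
                                 IRanges::IRanges(wh$start + 1L, wh$end))
    w <- vapply(fams, function(f) {
      inside <- IRanges::overlapsAny(gr, repeats[S4Vectors::mcols(repeats)$family == f],
                                     ignore.strand = TRUE)
      sum(wh$omega[inside])
    }, numeric(1))
    list(tot = tot, w = w)
  }
  a <- fam_weight(whits_a); b <- fam_weight(whits_b)
  res <- lapply(fams, function(f) {
    tab <- matrix(round(c(a$w[[f]], a$tot - a$w[[f]],
                          b$w[[f]], b$tot - b$w[[f]])), nrow = 2)
    ft <- if (all(tab >= 0) && sum(tab) > 0)
      fisher.test(tab) else list(estimate = NA_real_, p.value = NA_real_)
    data.frame(family = f,
               w_a = a$w[[f]], frac_a = if (a$tot > 0) a$w[[f]] / a$tot else 0,
               w_b = b$w[[f]], frac_b = if (b$tot > 0) b$w[[f]] / b$tot else 0,
               odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  })
  out <- do.call(rbind, res)
  names(out)[2:5] <- c(paste0("weight_", labels[1]), paste0("frac_", labels[1]),
                       paste0("weight_", labels[2]), paste0("frac_", labels[2]))
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$enriched <- !is.na(out$q_value) & out$q_value < 0.05
  rownames(out) <- NULL
  out
}
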