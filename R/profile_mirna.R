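#' Count reads per mature miRNA
#'
#' Every miRNA-classified tag is re-overlapped (same strand, at the
#' classification overlap threshold) with the mature-arm track and
#' contributes its full read count to each distinct mature miRNA it hits.
#' Tags that overlap only a hairpin (outside any mature arm) are counted
#' into a flagged `hairpin:<id>` bucket rather than silently dropped.
#'
#' @param classified classification table from [classify_tags()].
#' @param hits hit table from [match_tags()].
#' @param ann an `AnnotationSet` (mature + hairpin tracks are used).
#' @param min_overlap_frac minimum overlap as a fraction of tag length.
#' @return data.frame (feature, count, type) where type is "mature" or
#'   "hairpin".
#' @export
count_mature <- function(classified, hits, ann, min_overlap_frac = 0.8) {
  mir <- classified[classified$class == "miRNA", , drop = FALSE]
  empty <- data.frame(feature = character(0), count = numeric(0),
                      type = character(0))
  if (nrow(mir) == 0L) return(empty)
  h <- hits[hits$tag_id %in% mir$tag_id, , drop = FALSE]
  hgr <- hits_to_granges(h)
  cnt <- setNames(mir$count, mir$tag_id)
  tlen <- setNames(mir$length, mir$tag_id)

  overlap_pairs <- function(track) {
    if (is.null(track) || !length(track)) return(NULL)
    ov <- GenomicRanges::findOverlaps(hgr, track, ignore.strand = FALSE)
    if (!length(ov)) return(NULL)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(hgr)[qh], GenomicRanges::ranges(track)[sh]))
    tid <- S4Vectors::mcols(hgr)$tag_id[qh]
    keep <- w >= min_overlap_frac * tlen[tid]
    if (!any(keep)) return(NULL)
    unique(data.frame(tag_id = tid[keep],
                      feature = S4Vectors::mcols(track)$locus_id[sh[keep]]))
  }

  mp <- overlap_pairs(ann$mirna_mature)
  matured <- unique(mp$tag_id)
  res <- if (!is.null(mp)) {
    agg <- tapply(cnt[mp$tag_id], mp$feature, sum)
    data.frame(feature = names(agg), count = as.numeric(agg),
               type = "mature")
  } else empty
  # hairpin-only tags: flagged bucket
  rest <- setdiff(mir$tag_id, matured)
  if (length(rest)) {
    hp <- overlap_pairs(ann$mirna_hairpin)
    hp <- hp[hp$tag_id %in% rest, , drop = FALSE]
    if (!is.null(hp) && nrow(hp)) {
      agg <- tapply(cnt[hp$tag_id], hp$feature, sum)
      res <- rbind(res, data.frame(feature = paste0("hairpin:", names(agg)),
                                   count = as.numeric(agg),
                                   type = "hairpin"))
    }
  }
  res <- res[order(res$feature, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assemble a features-by-samples raw count matrix
#'
#' @param counts named list of per-sample count tables from
#'   [count_mature()]; mature features only are kept by default.
#' @param mature_only drop flagged hairpin buckets (default TRUE).
#' @return numeric matrix, features x samples.
#' @export
build_expression_matrix <- function(counts, mature_only = TRUE) {
  if (mature_only)
    counts <- lapply(counts, function(d) d[d$type == "mature", , drop = FALSE])
  feats <- sort(unique(unlist(lapply(counts, `[[`, "feature"))))
  m <- matrix(0, nrow = length(feats), ncol = length(counts),
              dimnames = list(feats, names(counts)))
  for (s in names(counts)) {
    d <- counts[[s]]
    m[d$feature, s] <- d$count
  }
  m
}

#' RPM-normalise a count matrix
#'
#' RPM = 1e6 * raw / library_size per sample. With the default denominator
#' (the per-sample column total, i.e. total miRNA-annotated reads) each
#' sample's RPM column sums to exactly 1e6. The log2 layer is log2(RPM)
#' with an optional pseudocount; with the default pseudocount of 0, zero
#' counts are NA in the log2 layer — the RPM >= 1 expression filter is
#' applied before any log-scale analysis, so zeros never reach it.
#'
#' @param raw numeric matrix, features x samples.
#' @param library_sizes per-sample denominators; defaults to column sums.
#' @param pseudocount added inside the log2 (default 0).
#' @return an `ExpressionMatrix`: list(raw, rpm, log2rpm, library_sizes).
#' @export
rpm_normalize <- function(raw, library_sizes = colSums(raw),
                          pseudocount = 0) {
  if (any(library_sizes <= 0)) stopf("library sizes must be positive")
  if (length(library_sizes) != ncol(raw))
    stopf("need one library size per sample")
  rpm <- sweep(raw, 2, library_sizes, "/") * 1e6
  l2 <- suppressWarnings(log2(rpm + pseudocount))
  l2[is.infinite(l2)] <- NA_real_
  structure(list(raw = raw, rpm = rpm, log2rpm = l2,
                 library_sizes = library_sizes),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples (libraries %s)\n",
              nrow(x$raw), ncol(x$raw),
              paste(format(x$library_sizes, big.mark = ","),
                    collapse = ", ")))
  invisible(x)
}

#' Call expressed features
#'
#' A feature is expressed in a sample when its RPM is at or above the
#' threshold (default 1 RPM).
#'
#' @param em an `ExpressionMatrix` or an RPM matrix.
#' @param threshold RPM expression threshold.
#' @return logical matrix, features x samples.
#' @export
call_expressed <- function(em, threshold = 1) {
  rpm <- if (inherits(em, "ExpressionMatrix")) em$rpm else em
  rpm >= threshold
}

#' Call cell-type-specific high-expression signatures
#'
#' A feature belongs to the focal sample's signature when it is expressed
#' there (RPM >= `min_rpm`) and its fold change against EVERY other sample
#' is at least `fold` (or against the mean of the others with
#' `vs = "mean"`). Fold changes are computed on the RPM scale with a
#' zero-guard: ratio = RPM_focal / max(RPM_other, eps), so an exact 2-fold
#' difference (e.g. 10 vs 5) passes at fold 2 while zero denominators stay
#' finite.
#'
#' @param em an `ExpressionMatrix`.
#' @param focal focal sample name.
#' @param others other sample names; default all remaining samples.
#' @param fold minimum fold change (> 1 for a real signature; exactly 1 is
#'   permitted and degenerates to "at least as high everywhere").
#' @param eps denominator floor in RPM units guarding zero denominators.
#' @param min_rpm focal expression threshold.
#' @param vs compare against "each" other sample (conjunction, default) or
#'   their "mean".
#' @return a `SignatureResult` data.frame: feature, focal RPM, fold change
#'   vs each other sample, min_fold; sorted by descending focal RPM.
#'   Attributes record focal, fold and eps.
#' @export
call_signature <- function(em, focal, others = NULL, fold = 2, eps = 0.5,
                           min_rpm = 1, vs = c("each", "mean")) {
  vs <- match.arg(vs)
  stopifnot(inherits(em, "ExpressionMatrix"))
  rpm <- em$rpm
  if (!focal %in% colnames(rpm)) stopf("unknown focal sample '%s'", focal)
  others <- others %||% setdiff(colnames(rpm), focal)
  if (focal %in% others) stopf("focal sample cannot be among the others")
  if (length(others) < 1) stopf("need at least one other sample")
  if (fold < 1) stopf("fold must be >= 1")

  f <- rpm[, focal]
  if (vs == "mean") {
    denom <- pmax(rowMeans(rpm[, others, drop = FALSE]), eps)
    fc <- matrix(f / denom, ncol = 1, dimnames = list(rownames(rpm), "mean"))
  } else {
    fc <- vapply(others, function(s) f / pmax(rpm[, s], eps),
                 numeric(nrow(rpm)))
    fc <- matrix(fc, nrow = nrow(rpm), dimnames = list(rownames(rpm), others))
  }
  minf <- apply(fc, 1, min)
  keep <- f >= min_rpm & minf >= fold
  out <- data.frame(feature = rownames(rpm)[keep], focal_rpm = f[keep],
                    fc[keep, , drop = FALSE], min_fold = minf[keep],
                    check.names = FALSE)
  colnames(out)[seq(3, 2 + ncol(fc))] <- paste0("fold_vs_", colnames(fc))
  out <- out[order(-out$focal_rpm, out$feature, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "focal") <- focal
  attr(out, "fold") <- fold
  attr(out, "eps") <- eps
  class(out) <- c("SignatureResult", "data.frame")
  out
}

#' Hierarchically cluster samples on log2 miRNA expression
#'
#' Features expressed (RPM >= `expressed_threshold`) in at least one sample
#' are kept, transformed to log2(RPM + pseudocount), and samples are
#' clustered with average linkage on correlation distance
#' (1 - Pearson r), the standard geometry of expression heat maps.
#'
#' @param em an `ExpressionMatrix`.
#' @param expressed_threshold RPM threshold for keeping a feature.
#' @param pseudocount added before log2 so zeros stay finite (default 1).
#' @return an [stats::hclust] object over samples.
#' @export
cluster_samples <- function(em, expressed_threshold = 1, pseudocount = 1) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  rpm <- em$rpm
  if (ncol(rpm) < 2) stopf("need at least 2 samples to cluster")
  keep <- rowSums(rpm >= expressed_threshold) >= 1
  if (!any(keep)) stopf("no feature is expressed in any sample")
  mat <- log2(rpm[keep, , drop = FALSE] + pseudocount)
  cc <- suppressWarnings(cor(mat, method = "pearson"))
  if (anyNA(cc))
    stopf("cannot cluster: a sample has zero variance over expressed features")
  hclust(as.dist(1 - cc), method = "average")
}
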