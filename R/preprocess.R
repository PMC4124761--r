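#' Trim 3' (and optionally 5') adapters from raw reads
#'
#' For each read the best-scoring semi-global alignment of the 3' adapter
#' against the read is found: the adapter may begin at any read position and
#' run off the read's end, the aligned overlap must be at least
#' `min_overlap` bases, and its mismatch fraction at most
#' `max_mismatch_rate`. Everything from the best adapter start onward is
#' removed (score = matches - mismatches, ties resolved toward the leftmost
#' start, i.e. the longest trim). Reads with no acceptable adapter match
#' pass through unchanged; downstream length filtering deals with them.
#' If a 5' adapter is given, a suffix of it found at the read's 5' end is
#' trimmed or the read is flagged as contaminant, per `adapter5_action`.
#'
#' Identical sequences are trimmed once and the result broadcast, so cost
#' scales with the number of distinct reads.
#'
#' @param reads data.frame (read_id, seq, qual) as from [read_fastq()], or a
#'   character vector of sequences.
#' @param adapter3 3' adapter sequence (required, non-empty).
#' @param adapter5 optional 5' adapter; `""` disables 5' handling.
#' @param min_overlap minimum adapter/read overlap in bases (>= 5).
#' @param max_mismatch_rate maximum mismatch fraction within the overlap.
#' @param adapter5_action `"trim"` removes a matched 5' adapter prefix,
#'   `"discard"` flags the read as contaminant instead.
#' @return data.frame (read_id, seq, qual) with logical columns `trimmed`
#'   (3' adapter found) and `contaminant` (5' adapter flagged under
#'   `"discard"`).
#' @export
trim_adapters <- function(reads, adapter3, adapter5 = "",
                          min_overlap = 6L, max_mismatch_rate = 0.1,
                          adapter5_action = c("trim", "discard")) {
  adapter5_action <- match.arg(adapter5_action)
  if (is.character(reads))
    reads <- data.frame(read_id = paste0("r", seq_along(reads)), seq = reads,
                        qual = strrep("I", nchar(reads)))
  if (nchar(adapter3) == 0) stopf("adapter3 must be non-empty")
  if (min_overlap < 5) stopf("min_overlap must be >= 5")

  seqs <- as.character(reads$seq)
  uniq <- unique(seqs)
  cut3 <- adapter_cut_positions(uniq, adapter3, min_overlap, max_mismatch_rate)
  cut5 <- if (nzchar(adapter5))
    adapter5_prefix_len(uniq, adapter5, min_overlap, max_mismatch_rate)
  else rep(0L, length(uniq))

  m <- match(seqs, uniq)
  keep_to <- cut3[m]            # last insert base (0 = all adapter)
  trimmed <- keep_to < nchar(seqs)
  from <- cut5[m] + 1L
  contaminant <- rep(FALSE, length(seqs))
  if (nzchar(adapter5) && adapter5_action == "discard") {
    contaminant <- cut5[m] > 0L
    from <- rep(1L, length(seqs))
  }
  out <- data.frame(read_id = reads$read_id,
                    seq = substr(seqs, from, keep_to),
                    qual = substr(as.character(reads$qual), from, keep_to))
  out$trimmed <- trimmed
  out$contaminant <- contaminant
  out
}

# For each unique sequence, the 0-based length of the insert kept after the
# best 3' adapter match (= nchar(seq) when no acceptable match exists).
adapter_cut_positions <- function(seqs, adapter, min_overlap, max_rate) {
  res <- nchar(seqs)
  a <- strsplit(adapter, "", fixed = TRUE)[[1]]
  la <- length(a)
  for (L in unique(nchar(seqs))) {
    sel <- which(nchar(seqs) == L)
    if (L < min_overlap) next
    mm <- matrix(unlist(strsplit(seqs[sel], "", fixed = TRUE), use.names = FALSE),
                 nrow = length(sel), byrow = TRUE)
    best_score <- rep(-Inf, length(sel))
    best_cut <- rep(L, length(sel))
    for (i in seq_len(L - min_overlap + 1L)) {
      ov <- min(la, L - i + 1L)
      if (ov < min_overlap) break
      mism <- integer(length(sel))
      for (p in seq_len(ov)) mism <- mism + (mm[, i + p - 1L] != a[p])
      score <- ov - 2L * mism
      ok <- (mism / ov <= max_rate) & (score > best_score)
      best_score[ok] <- score[ok]
      best_cut[ok] <- i - 1L
    }
    res[sel] <- best_cut
  }
  res
}

# Length of a 5' adapter suffix matched at the read start (0 = none).
adapter5_prefix_len <- function(seqs, adapter5, min_overlap, max_rate) {
  la <- nchar(adapter5)
  res <- integer(length(seqs))
  if (length(seqs) == 0L) return(res)
  top <- min(la, max(nchar(seqs)))
  if (top < min_overlap) return(res)
  for (ov in seq(top, min_overlap)) {
    idx <- which(res == 0L & nchar(seqs) >= ov)
    if (!length(idx)) next
    asuf <- substr(adapter5, la - ov + 1L, la)
    pre <- substr(seqs[idx], 1L, ov)
    mism <- mapply(function(x, y) sum(utf8ToInt(x) != utf8ToInt(y)),
                   pre, asuf)
    hit <- mism / ov <= max_rate
    res[idx[hit]] <- ov
  }
  res
}

#' Filter trimmed reads into clean reads
#'
#' Applies the clean-read rules: reject contaminants (5'-adapter flags and
#' optional exact-substring matches to a user-supplied contaminant set),
#' reads outside the retained length window (the library is gel-selected to
#' 18–40 nt, and anything shorter than 18 nt is inadequate), and low-quality
#' reads (any ambiguous N base, or mean Phred below `min_mean_quality`).
#' Each read is charged to exactly one rejection category, so the ledger
#' balances: raw = clean + contaminant + length + quality.
#'
#' @param reads trimmed reads from [trim_adapters()] (or any data.frame with
#'   read_id, seq, qual; missing `contaminant`/`trimmed` columns default to
#'   FALSE).
#' @param min_len,max_len retained length window, inclusive.
#' @param min_mean_quality minimum mean Phred score.
#' @param contaminants optional character vector of contaminant sequences; a
#'   read containing any of them as an exact substring is rejected.
#' @return a `CleanReadSet`: list with `reads` (data.frame read_id, seq,
#'   qual) and `stats` (raw, adapter_trimmed, contaminant, length_rejected,
#'   quality_rejected, clean).
#' @export
filter_clean <- function(reads, min_len = 18L, max_len = 40L,
                         min_mean_quality = 20, contaminants = NULL) {
  if (min_len > max_len) stopf("min_len must be <= max_len")
  n <- nrow(reads)
  contam <- if ("contaminant" %in% names(reads)) reads$contaminant
            else rep(FALSE, n)
  if (!is.null(contaminants) && n > 0) {
    for (cs in contaminants) contam <- contam | grepl(cs, reads$seq, fixed = TRUE)
  }
  len <- nchar(reads$seq)
  len_bad <- !contam & (len < min_len | len > max_len)
  has_n <- grepl("[^ACGT]", reads$seq)
  qual_bad <- !contam & !len_bad &
    (has_n | mean_phred(reads$qual) < min_mean_quality)
  clean <- !contam & !len_bad & !qual_bad
  stats <- list(raw = n,
                adapter_trimmed = sum(reads$trimmed %||% logical(n)),
                contaminant = sum(contam),
                length_rejected = sum(len_bad),
                quality_rejected = sum(qual_bad),
                clean = sum(clean))
  structure(list(reads = reads[clean, c("read_id", "seq", "qual")],
                 stats = stats),
            class = "CleanReadSet")
}

#' @export
print.CleanReadSet <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0("CleanReadSet: %d clean of %d raw ",
                     "(%d trimmed, %d contaminant, %d length, %d quality)\n"),
              s$clean, s$raw, s$adapter_trimmed, s$contaminant,
              s$length_rejected, s$quality_rejected))
  invisible(x)
}

#' Collapse clean reads into unique tags
#'
#' One tag per distinct sequence, carrying its copy number among the clean
#' reads. Tags are ordered by descending count, then lexicographically, and
#' named `t<rank>_x<count>`. The collapse is lossless: expanding tags by
#' count recovers the clean-read multiset.
#'
#' @param clean a `CleanReadSet`, or a data.frame/character vector of
#'   sequences.
#' @return TagSet data.frame (tag_id, seq, count).
#' @export
collapse_reads <- function(clean) {
  seqs <- if (inherits(clean, "CleanReadSet")) clean$reads$seq
          else if (is.data.frame(clean)) clean$seq
          else clean
  if (length(seqs) == 0L)
    return(data.frame(tag_id = character(0), seq = character(0),
                      count = integer(0)))
  tab <- table(seqs)
  df <- data.frame(seq = names(tab), count = as.integer(tab))
  df <- df[order(-df$count, df$seq, method = "radix"), , drop = FALSE]
  df$tag_id <- sprintf("t%d_x%d", seq_len(nrow(df)), df$count)
  rownames(df) <- NULL
  df[, c("tag_id", "seq", "count")]
}

#' Preprocess raw reads end to end
#'
#' Convenience wrapper: adapter trimming, clean-read filtering, collapsing.
#'
#' @inheritParams trim_adapters
#' @inheritParams filter_clean
#' @return list with `tags` (TagSet), `clean` (`CleanReadSet`) and `stats`.
#' @export
preprocess_reads <- function(reads, adapter3, adapter5 = "",
                             min_overlap = 6L, max_mismatch_rate = 0.1,
                             min_len = 18L, max_len = 40L,
                             min_mean_quality = 20, contaminants = NULL) {
  tr <- trim_adapters(reads, adapter3, adapter5, min_overlap,
                      max_mismatch_rate)
  cl <- filter_clean(tr, min_len, max_len, min_mean_quality, contaminants)
  list(tags = collapse_reads(cl), clean = cl, stats = cl$stats)
}
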