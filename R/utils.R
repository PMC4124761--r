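#' @importFrom stats rbinom rgamma runif setNames cor p.adjust fisher.test
#'   hclust as.dist
#' @importFrom utils head read.table write.table
NULL

#' Round half away from zero
#'
#' Fixed-point rounding where ties go up (0.005 -> 0.01), matching how
#' percentages are conventionally printed in sequencing summary tables.
#' Base R's `round()` rounds half to even and is not suitable here.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reverse complement of DNA character strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequences
#'
#' Uniform i.i.d. A/C/G/T strings of the given lengths, drawn from the
#' current RNG stream (seed control is the caller's responsibility).
#'
#' @param lengths integer vector of sequence lengths.
#' @return character vector of DNA sequences, one per length.
#' @export
random_dna <- function(lengths) {
  if (length(lengths) == 0) return(character(0))
  total <- sum(lengths)
  bases <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1
  vapply(seq_along(lengths),
         function(i) paste(bases[starts[i]:ends[i]], collapse = ""),
         character(1))
}

# Mean Phred score of a quality string (Phred+33 encoding).
mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (nchar(q) == 0) return(NA_real_)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}

# The small-RNA class vocabulary, in annotation priority order. Structural
# classes share one priority tier; endo-siRNA is assigned by rule, last.
#' Annotation class priority tiers
#'
#' The fixed hierarchical annotation order used throughout the package:
#' miRNA first, then the structural RNA tier (rRNA/snoRNA/tRNA/scRNA/snRNA),
#' then piRNA; endo-siRNAs are assigned last, by rule rather than by track.
#'
#' @return list of character vectors, one per priority tier.
#' @export
class_priority <- function() {
  list(miRNA = "miRNA",
       structural = c("rRNA", "snoRNA", "tRNA", "scRNA", "snRNA"),
       piRNA = "piRNA")
}

structural_classes <- function() class_priority()$structural

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
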