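#' Default five-cell-type simulation profiles
#'
#' Encodes the qualitative contrasts between the five libraries the
#' pipeline is designed around (embryonic stem cells, spermatogonial stem
#' cells, developing germ cells, somatic testis cells, mesenchymal stem
#' cells):
#' \itemize{
#'   \item miRNA is the dominant class (~60% of annotated reads) in
#'     every sample except the developing germ cells, where piRNA is modal;
#'   \item piRNA abundance is ordered GC > SSC > ESC > ST > MSC, with MSC
#'     piRNA near zero;
#'   \item endo-siRNA abundance is ordered ESC > SSC > GC;
#'   \item ESC and SSC share a correlated miRNA expression program, as do
#'     ST and MSC, while GC has its own — so correlation-based clustering
#'     pairs SSC with ESC and ST with MSC.
#' }
#' Per-locus miRNA weights are drawn from a heavy-tailed gamma and shared
#' (with log-normal wobble) within the ESC/SSC and ST/MSC pairs.
#'
#' @param bundle a `GenomeBundle` (locus counts determine weight lengths).
#' @param seed integer seed; sample seeds are derived from it.
#' @param n_reads reads per sample recorded in the profile (informational).
#' @param error_rate per-base substitution rate applied to all samples.
#' @return named list of five [cell_profile()] objects
#'   (ESC, SSC, GC, ST, MSC).
#' @export
default_cell_profiles <- function(bundle, seed = 1L, n_reads = 50000L,
                                  error_rate = 0) {
  mixes <- list(
    ESC = c(miRNA = 0.58, piRNA = 0.080, siRNA = 0.12, rRNA = 0.05,
            snoRNA = 0.03, tRNA = 0.04, scRNA = 0.01, snRNA = 0.010,
            other = 0.08),
    SSC = c(miRNA = 0.55, piRNA = 0.150, siRNA = 0.08, rRNA = 0.05,
            snoRNA = 0.03, tRNA = 0.04, scRNA = 0.01, snRNA = 0.010,
            other = 0.08),
    GC  = c(miRNA = 0.18, piRNA = 0.550, siRNA = 0.03, rRNA = 0.05,
            snoRNA = 0.03, tRNA = 0.04, scRNA = 0.01, snRNA = 0.010,
            other = 0.10),
    ST  = c(miRNA = 0.60, piRNA = 0.050, siRNA = 0.05, rRNA = 0.07,
            snoRNA = 0.04, tRNA = 0.05, scRNA = 0.02, snRNA = 0.020,
            other = 0.10),
    MSC = c(miRNA = 0.62, piRNA = 0.015, siRNA = 0.06, rRNA = 0.07,
            snoRNA = 0.04, tRNA = 0.05, scRNA = 0.02, snRNA = 0.015,
            other = 0.11))
  n_mat <- length(bundle$annotation$mirna_mature)
  wobble <- function(base, sd) base * exp(stats::rnorm(n_mat, 0, sd))
  weights <- withr::with_seed(seed, {
    prog_germ <- rgamma(n_mat, shape = 0.8, rate = 1) + 0.02
    prog_soma <- rgamma(n_mat, shape = 0.8, rate = 1) + 0.02
    prog_gc <- rgamma(n_mat, shape = 0.8, rate = 1) + 0.02
    list(ESC = wobble(prog_germ, 0.25), SSC = wobble(prog_germ, 0.25),
         GC = wobble(prog_gc, 0.25), ST = wobble(prog_soma, 0.25),
         MSC = wobble(prog_soma, 0.25))
  })
  out <- lapply(names(mixes), function(s) {
    cell_profile(label = s, class_mix = mixes[[s]],
                 expression_weights = list(miRNA = weights[[s]]),
                 error_rate = error_rate,
                 seed = (seed * 7L + match(s, names(mixes))) %% .Machine$integer.max)
  })
  names(out) <- names(mixes)
  attr(out, "n_reads") <- n_reads
  out
}
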