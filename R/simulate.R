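#' Parameters for a toy genome
#'
#' Assembles the locus-count/length specification consumed by
#' [build_toy_genome()]. Defaults give a 100 kb single-chromosome genome with
#' enough loci of every small-RNA class to exercise the whole pipeline:
#' miRNA hairpins with nested mature arms, structural RNA loci
#' (rRNA/snoRNA/tRNA/scRNA/snRNA), single-stranded piRNA clusters (optionally
#' embedded in ERV repeats and optionally present as identical multi-copy
#' groups, which creates genuine multi-mapping reads), free-standing repeat
#' elements that serve as endo-siRNA source loci, and plain intergenic
#' windows for unannotated background reads.
#'
#' @param chrom_len length of each chromosome in bp.
#' @param n_chrom number of chromosomes.
#' @param n_mirna number of miRNA hairpins.
#' @param hairpin_len hairpin length (must fit two mature arms).
#' @param mature_len mature miRNA length.
#' @param p_mature3p probability a hairpin also carries a 3p arm.
#' @param n_structural named integer vector of locus counts per structural
#'   class (names drawn from rRNA/snoRNA/tRNA/scRNA/snRNA).
#' @param structural_len structural locus length.
#' @param n_pirna number of piRNA clusters.
#' @param pirna_len piRNA cluster length.
#' @param pirna_copies identical-sequence copies per piRNA cluster group
#'   (1 = all clusters unique; >1 plants multi-mapping piRNA reads).
#' @param p_pirna_in_repeat probability a piRNA cluster is wrapped in an
#'   ERV1/ERV2/ERV3 repeat interval.
#' @param repeat_families repeat family labels for free-standing repeats.
#' @param n_repeats_per_family free-standing repeats per family.
#' @param repeat_len free-standing repeat length.
#' @param n_other intergenic background windows.
#' @param other_len background window length.
#' @param margin minimum gap enforced between placed loci, bp.
#' @return a list of class `toy_genome_spec`.
#' @export
toy_genome_spec <- function(chrom_len = 100000L, n_chrom = 1L,
                            n_mirna = 20L, hairpin_len = 80L,
                            mature_len = 22L, p_mature3p = 0.7,
                            n_structural = c(rRNA = 4L, snoRNA = 4L,
                                             tRNA = 4L, scRNA = 2L,
                                             snRNA = 2L),
                            structural_len = 150L,
                            n_pirna = 6L, pirna_len = 1200L,
                            pirna_copies = 2L, p_pirna_in_repeat = 0.8,
                            repeat_families = c("ERV1", "ERV2", "ERV3",
                                                "LINE", "SINE"),
                            n_repeats_per_family = 3L, repeat_len = 400L,
                            n_other = 8L, other_len = 300L,
                            margin = 10L) {
  if (hairpin_len < 2 * mature_len + 20)
    stopf("hairpin_len must be >= 2*mature_len + 20 to fit both arms")
  bad <- setdiff(names(n_structural), structural_classes())
  if (length(bad)) stopf("unknown structural class: %s", paste(bad, collapse = ", "))
  structure(as.list(environment()), class = "toy_genome_spec")
}

# Rejection-sampling placement of one interval of length `len` on one of the
# chromosomes, keeping `margin` bp clear of everything already placed.
place_locus <- function(chrom_lens, occupied, len, margin, max_try = 500L) {
  for (i in seq_len(max_try)) {
    chrom <- sample(names(chrom_lens), 1, prob = chrom_lens)
    L <- chrom_lens[[chrom]]
    if (L < len) next
    s <- sample.int(L - len + 1L, 1L)
    e <- s + len - 1L
    occ <- occupied[[chrom]]
    if (is.null(occ) || nrow(occ) == 0L ||
        all(s > occ$end + margin | e < occ$start - margin)) {
      return(list(chrom = chrom, start = s, end = e))
    }
  }
  stopf("genome too small: failed to place a %d bp locus after %d tries",
        len, max_try)
}

#' Build a toy genome with ground-truth annotation tracks
#'
#' Generates a random genome and places mutually non-overlapping loci for
#' every annotated small-RNA class, so that a read's class of origin is
#' unambiguous and downstream recovery tests can be exact. piRNA clusters may
#' be wrapped in ERV repeat intervals and grouped into identical-sequence
#' copies (same strand within a group), producing true multi-mapping reads
#' whose hits are all piRNA-cluster hits. Free-standing repeats (never
#' overlapping any class track) double as endo-siRNA source loci.
#'
#' @param spec a [toy_genome_spec()].
#' @param seed integer RNG seed; the same (spec, seed) pair always yields a
#'   byte-identical bundle.
#' @return a `GenomeBundle`: list with `genome` (named
#'   [Biostrings::DNAStringSet]), `annotation` (an [annotation_set()]),
#'   `repeats` (GRanges with a `family` column), `other` (GRanges of
#'   background windows) and the originating `spec`.
#' @export
build_toy_genome <- function(spec = toy_genome_spec(), seed = 1L) {
  stopifnot(inherits(spec, "toy_genome_spec"))
  withr::with_seed(seed, build_toy_genome_impl(spec))
}

build_toy_genome_impl <- function(spec) {
  chrom_names <- paste0("chr", seq_len(spec$n_chrom))
  chrom_lens <- setNames(rep(spec$chrom_len, spec$n_chrom), chrom_names)
  occupied <- setNames(vector("list", spec$n_chrom), chrom_names)
  note <- function(p) {
    occupied[[p$chrom]] <<- rbind(occupied[[p$chrom]],
                                  data.frame(start = p$start, end = p$end))
    p
  }
  rand_strand <- function(n) sample(c("+", "-"), n, replace = TRUE)

  # -- miRNA hairpins + nested mature arms ---------------------------------
  hp <- vector("list", spec$n_mirna)
  mat <- list()
  hp_strand <- rand_strand(spec$n_mirna)
  for (i in seq_len(spec$n_mirna)) {
    p <- note(place_locus(chrom_lens, occupied, spec$hairpin_len, spec$margin))
    id <- paste0("mir", i)
    hp[[i]] <- data.frame(chrom = p$chrom, start = p$start, end = p$end,
                          strand = hp_strand[i], locus_id = id)
    m5 <- data.frame(chrom = p$chrom, start = p$start + 9L,
                     end = p$start + 9L + spec$mature_len - 1L,
                     strand = hp_strand[i],
                     locus_id = paste0(id, "-5p"), parent = id)
    mat[[length(mat) + 1L]] <- m5
    if (runif(1) < spec$p_mature3p) {
      mat[[length(mat) + 1L]] <- data.frame(
        chrom = p$chrom, start = p$end - 9L - spec$mature_len + 1L,
        end = p$end - 9L, strand = hp_strand[i],
        locus_id = paste0(id, "-3p"), parent = id)
    }
  }

  # -- structural RNA loci --------------------------------------------------
  struct <- list()
  for (cls in names(spec$n_structural)) {
    n <- spec$n_structural[[cls]]
    if (n == 0L) next
    st <- rand_strand(n)
    for (i in seq_len(n)) {
      p <- note(place_locus(chrom_lens, occupied, spec$structural_len,
                            spec$margin))
      struct[[length(struct) + 1L]] <- data.frame(
        chrom = p$chrom, start = p$start, end = p$end, strand = st[i],
        locus_id = paste0(tolower(cls), i), class = cls)
    }
  }

  # -- piRNA clusters (placed with flanks so a wrapping repeat fits) -------
  flank <- 20L
  pir <- vector("list", spec$n_pirna)
  pir_rep <- list()
  n_groups <- if (spec$n_pirna) ceiling(spec$n_pirna / spec$pirna_copies) else 0L
  group_of <- if (spec$n_pirna) rep(seq_len(n_groups), each = spec$pirna_copies,
                                    length.out = spec$n_pirna) else integer(0)
  group_strand <- rand_strand(n_groups)
  for (i in seq_len(spec$n_pirna)) {
    p <- note(place_locus(chrom_lens, occupied, spec$pirna_len + 2L * flank,
                          spec$margin))
    cs <- p$start + flank; ce <- p$end - flank
    pir[[i]] <- data.frame(chrom = p$chrom, start = cs, end = ce,
                           strand = group_strand[group_of[i]],
                           locus_id = paste0("pi", i), group = group_of[i])
    if (runif(1) < spec$p_pirna_in_repeat) {
      fam <- sample(intersect(c("ERV1", "ERV2", "ERV3"), spec$repeat_families), 1)
      pir_rep[[length(pir_rep) + 1L]] <- data.frame(
        chrom = p$chrom, start = p$start, end = p$end,
        strand = group_strand[group_of[i]],
        family = fam, locus_id = paste0("rep_", fam, "_pi", i))
    }
  }

  # -- free-standing repeats (endo-siRNA sources) --------------------------
  reps <- list()
  for (fam in spec$repeat_families) {
    n <- spec$n_repeats_per_family
    if (n == 0L) next
    st <- rand_strand(n)
    for (i in seq_len(n)) {
      p <- note(place_locus(chrom_lens, occupied, spec$repeat_len, spec$margin))
      reps[[length(reps) + 1L]] <- data.frame(
        chrom = p$chrom, start = p$start, end = p$end, strand = st[i],
        family = fam, locus_id = paste0("rep_", fam, "_", i))
    }
  }

  # -- intergenic background windows ---------------------------------------
  oth <- vector("list", spec$n_other)
  if (spec$n_other) {
    st <- rand_strand(spec$n_other)
    for (i in seq_len(spec$n_other)) {
      p <- note(place_locus(chrom_lens, occupied, spec$other_len, spec$margin))
      oth[[i]] <- data.frame(chrom = p$chrom, start = p$start, end = p$end,
                             strand = st[i], locus_id = paste0("other", i))
    }
  }

  # -- genome sequence; identical-copy piRNA groups written in last --------
  genome_chr <- setNames(random_dna(chrom_lens), chrom_names)
  pir_df <- if (length(pir)) do.call(rbind, pir) else NULL
  if (!is.null(pir_df) && spec$pirna_copies > 1L) {
    for (g in unique(pir_df$group)) {
      idx <- which(pir_df$group == g)
      if (length(idx) < 2L) next
      m <- pir_df[idx[1L], ]
      master <- substr(genome_chr[[m$chrom]], m$start, m$end)
      for (j in idx[-1L]) {
        r <- pir_df[j, ]
        substr(genome_chr[[r$chrom]], r$start, r$end) <- master
      }
    }
  }

  si <- GenomeInfoDb::Seqinfo(seqnames = chrom_names,
                              seqlengths = unname(chrom_lens))
  as_gr <- function(df, extra_cols = character(0)) {
    if (is.null(df) || !NROW(df)) {
      gr <- GenomicRanges::GRanges(seqinfo = si)
      for (cc in c("locus_id", extra_cols))
        S4Vectors::mcols(gr)[[cc]] <- character(0)
      return(gr)
    }
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end),
                                 strand = df$strand, seqinfo = si)
    S4Vectors::mcols(gr)$locus_id <- df$locus_id
    for (cc in extra_cols) S4Vectors::mcols(gr)[[cc]] <- df[[cc]]
    gr
  }
  struct_df <- if (length(struct)) do.call(rbind, struct) else NULL
  struct_grs <- setNames(lapply(structural_classes(), function(cls) {
    as_gr(if (is.null(struct_df)) NULL else struct_df[struct_df$class == cls, ])
  }), structural_classes())

  ann <- annotation_set(
    mirna_hairpin = as_gr(if (length(hp)) do.call(rbind, hp) else NULL),
    mirna_mature = as_gr(if (length(mat)) do.call(rbind, mat) else NULL,
                         "parent"),
    structural = struct_grs,
    pirna = as_gr(pir_df))

  rep_df <- rbind(
    if (length(reps)) do.call(rbind, reps) else NULL,
    if (length(pir_rep)) do.call(rbind, pir_rep) else NULL)
  repeats <- as_gr(rep_df, "family")

  structure(list(genome = Biostrings::DNAStringSet(genome_chr),
                 annotation = ann,
                 repeats = repeats,
                 other = as_gr(if (spec$n_other) do.call(rbind, oth) else NULL),
                 spec = spec),
            class = "GenomeBundle")
}

#' @export
print.GenomeBundle <- function(x, ...) {
  cat("GenomeBundle:", length(x$genome), "chromosome(s),",
      sum(Biostrings::width(x$genome)), "bp\n")
  cat("  miRNA hairpins:", length(x$annotation$mirna_hairpin),
      " matures:", length(x$annotation$mirna_mature), "\n")
  cat("  structural loci:",
      sum(vapply(x$annotation$structural, length, integer(1))), "\n")
  cat("  piRNA clusters:", length(x$annotation$pirna),
      " repeats:", length(x$repeats), "\n")
  invisible(x)
}

# Loci a sample can emit reads from, per simulation class.
emission_loci <- function(bundle, class) {
  ann <- bundle$annotation
  switch(class,
         miRNA = ann$mirna_mature,
         piRNA = ann$pirna,
         siRNA = sirna_source_loci(bundle),
         other = bundle$other,
         {
           if (!class %in% structural_classes())
             stopf("unknown simulation class: %s", class)
           ann$structural[[class]]
         })
}

#' Repeat loci usable as endo-siRNA sources
#'
#' Free-standing repeats, i.e. repeat intervals that do not overlap any piRNA
#' cluster. Reads emitted from them are repeat-derived but belong to no
#' annotated class track, which is exactly the endo-siRNA screen's target.
#'
#' @param bundle a `GenomeBundle`.
#' @return GRanges of repeat intervals.
#' @export
sirna_source_loci <- function(bundle) {
  r <- bundle$repeats
  r[!IRanges::overlapsAny(r, bundle$annotation$pirna, ignore.strand = TRUE)]
}

#' Default per-class read-length distributions
#'
#' miRNA reads peak at 22–23 nt and piRNA reads at 27–30 nt, the canonical
#' length signatures of the two classes; endo-siRNAs sit at 20–22 nt,
#' structural RNA fragments are broad (24–33 nt), and background reads span
#' 15–34 nt so that the <18 nt clean-read filter is exercised.
#'
#' @return named list: class -> named probability vector (names are lengths).
#' @export
default_length_models <- function() {
  unif <- function(lens) setNames(rep(1 / length(lens), length(lens)), lens)
  c(list(miRNA = c("22" = 0.6, "23" = 0.4),
         piRNA = c("27" = 0.2, "28" = 0.3, "29" = 0.3, "30" = 0.2),
         siRNA = c("20" = 0.3, "21" = 0.4, "22" = 0.3),
         other = unif(15:34)),
    setNames(rep(list(unif(24:33)), length(structural_classes())),
             structural_classes()))
}

#' Describe a cell-type library for simulation
#'
#' @param label sample name.
#' @param class_mix named proportions over simulation classes (miRNA,
#'   rRNA/snoRNA/tRNA/scRNA/snRNA, piRNA, siRNA, other); must sum to 1.
#' @param length_model per-class read-length distributions; see
#'   [default_length_models()].
#' @param expression_weights optional named list class -> per-locus sampling
#'   weights (parallel to the bundle's loci for that class); default uniform.
#' @param adapter3 3' adapter sequence, appended to every insert (the library
#'   is read through the adapter, as in real small-RNA sequencing).
#' @param adapter5 optional 5' adapter, prepended; empty by default.
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param read_length machine read length; the adapter-ligated molecule is
#'   truncated to this many cycles.
#' @param base_quality constant Phred score given to every base.
#' @param seed RNG seed for this sample's read draw.
#' @return list of class `cell_profile`.
#' @export
cell_profile <- function(label, class_mix,
                         length_model = default_length_models(),
                         expression_weights = NULL,
                         adapter3 = "TGGAATTCTCGGGTGCCAAGGAACTCCAGTCAC",
                         adapter5 = "",
                         error_rate = 0, read_length = 40L,
                         base_quality = 37L, seed = 1L) {
  if (any(class_mix < 0)) stopf("class_mix proportions must be non-negative")
  if (abs(sum(class_mix) - 1) > 1e-9) stopf("class_mix must sum to 1")
  if (error_rate < 0 || error_rate >= 1) stopf("error_rate must be in [0, 1)")
  if (nchar(adapter3) == 0) stopf("adapter3 must be non-empty")
  structure(as.list(environment()), class = "cell_profile")
}

#' Simulate one small-RNA library with ground truth
#'
#' Draws reads class-by-class from the bundle's loci: the class of each read
#' is a multinomial draw from `class_mix`, the source locus is drawn with the
#' profile's per-locus weights, the insert is the genomic subsequence on the
#' locus strand (piRNA reads come only from the cluster's annotated strand;
#' miRNA reads start at the mature arm's 5' end), adapters are ligated and
#' the molecule truncated to the machine read length, and substitution
#' errors are injected at `error_rate`. Every emitted read is logged in a
#' truth table (class, source locus, strand, insert length).
#'
#' @param bundle a `GenomeBundle` from [build_toy_genome()].
#' @param profile a [cell_profile()].
#' @param n_reads number of reads to emit.
#' @return list with `reads` (data.frame: read_id, seq, qual) and `truth`
#'   (data.frame: read_id, class, locus_id, strand, insert_len).
#' @export
simulate_sample <- function(bundle, profile, n_reads) {
  stopifnot(inherits(bundle, "GenomeBundle"), inherits(profile, "cell_profile"),
            n_reads >= 0)
  withr::with_seed(profile$seed, simulate_sample_impl(bundle, profile, n_reads))
}

simulate_sample_impl <- function(bundle, profile, n_reads) {
  empty <- list(
    reads = data.frame(read_id = character(0), seq = character(0),
                       qual = character(0)),
    truth = data.frame(read_id = character(0), class = character(0),
                       locus_id = character(0), strand = character(0),
                       insert_len = integer(0)))
  if (n_reads == 0L) return(empty)

  mix <- profile$class_mix[profile$class_mix > 0]
  loci <- lapply(names(mix), function(cls) {
    g <- emission_loci(bundle, cls)
    if (length(g) == 0L)
      stopf("profile '%s' requests class '%s' but the bundle has no such loci",
            profile$label, cls)
    g
  })
  names(loci) <- names(mix)

  chrom_chr <- setNames(as.character(bundle$genome), names(bundle$genome))
  cls_draw <- sample(names(mix), n_reads, replace = TRUE, prob = mix)

  parts <- lapply(names(mix), function(cls) {
    idx <- which(cls_draw == cls)
    n <- length(idx)
    if (n == 0L) return(NULL)
    g <- loci[[cls]]
    w <- profile$expression_weights[[cls]] %||% rep(1, length(g))
    if (length(w) != length(g))
      stopf("expression_weights for class '%s' has length %d, expected %d",
            cls, length(w), length(g))
    li <- sample.int(length(g), n, replace = TRUE, prob = w)
    lm <- profile$length_model[[cls]]
    if (is.null(lm)) stopf("no length model for class '%s'", cls)
    len <- as.integer(sample(names(lm), n, replace = TRUE, prob = lm))
    ls <- GenomicRanges::start(g)[li]; le <- GenomicRanges::end(g)[li]
    lw <- le - ls + 1L
    if (cls != "miRNA") len <- pmin(len, lw)
    locus_strand <- as.character(GenomicRanges::strand(g))[li]
    strand <- if (cls %in% c("siRNA", "other"))
      sample(c("+", "-"), n, replace = TRUE) else locus_strand
    if (cls == "miRNA") {
      # anchored at the mature 5' end (strand-aware); may run a base or two
      # into the hairpin when the drawn length exceeds the mature arm
      s <- ifelse(strand == "+", ls, le - len + 1L)
      e <- ifelse(strand == "+", ls + len - 1L, le)
    } else {
      off <- floor(runif(n) * (lw - len + 1))
      s <- ls + as.integer(off)
      e <- s + len - 1L
    }
    chrom <- as.character(GenomicRanges::seqnames(g))[li]
    ins <- substring(chrom_chr[chrom], s, e)
    neg <- strand == "-"
    if (any(neg)) ins[neg] <- revcomp(ins[neg])
    data.frame(idx = idx, class = cls,
               locus_id = S4Vectors::mcols(g)$locus_id[li],
               strand = strand, insert = ins, insert_len = len)
  })
  dd <- do.call(rbind, parts)
  dd <- dd[order(dd$idx), , drop = FALSE]

  full <- paste0(profile$adapter5, dd$insert, profile$adapter3)
  reads <- substr(full, 1L, profile$read_length)

  if (profile$error_rate > 0) {
    n_err <- rbinom(length(reads), nchar(reads), profile$error_rate)
    for (i in which(n_err > 0L)) {
      pos <- sample.int(nchar(reads[i]), n_err[i])
      ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      reads[i] <- paste(ch, collapse = "")
    }
  }

  ids <- sprintf("%s_r%06d", profile$label, seq_len(n_reads))
  qual <- strrep(intToUtf8(profile$base_quality + 33L), nchar(reads))
  list(reads = data.frame(read_id = ids, seq = reads, qual = qual),
       truth = data.frame(read_id = ids, class = dd$class,
                          locus_id = dd$locus_id, strand = dd$strand,
                          insert_len = dd$insert_len))
}
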