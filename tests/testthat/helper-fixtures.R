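# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A small bundle for module-level tests (fast to simulate against).
small_spec <- function() {
  toy_genome_spec(chrom_len = 30000L, n_mirna = 8L,
                  n_structural = c(rRNA = 2L, snoRNA = 2L, tRNA = 2L,
                                   scRNA = 1L, snRNA = 1L),
                  n_pirna = 4L, pirna_len = 600L, pirna_copies = 2L,
                  n_repeats_per_family = 2L, repeat_len = 250L,
                  n_other = 4L, other_len = 250L)
}

small_bundle <- function() cached("small_bundle", build_toy_genome(small_spec(), seed = 11))

# One fully processed small sample (GC-like mix: every class present).
small_run <- function() cached("small_run", {
  b <- small_bundle()
  prof <- cell_profile("S1",
                       c(miRNA = 0.35, piRNA = 0.3, siRNA = 0.1,
                         rRNA = 0.05, snoRNA = 0.05, tRNA = 0.05,
                         scRNA = 0.02, snRNA = 0.03, other = 0.05),
                       seed = 5)
  sim <- simulate_sample(b, prof, 8000)
  pp <- preprocess_reads(sim$reads, prof$adapter3)
  idx <- build_index(b)
  hits <- match_tags(idx, pp$tags)
  cl <- classify_tags(pp$tags, hits, b$annotation, b$repeats)
  list(bundle = b, profile = prof, sim = sim, pp = pp, idx = idx,
       hits = hits, classified = cl)
})

# ---- independent exact-match oracle (string scan, no Biostrings) ---------

oracle_rc <- function(x) {
  vapply(x, function(s)
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")),
    character(1), USE.NAMES = FALSE)
}

# All (overlapping) 1-based occurrences of fixed pattern `pat` in `text`.
oracle_find_all <- function(text, pat) {
  res <- integer(0)
  from <- 1L
  n <- nchar(text); lp <- nchar(pat)
  while (from + lp - 1L <= n) {
    m <- regexpr(pat, substr(text, from, n), fixed = TRUE)
    if (m < 0L) break
    pos <- from + as.integer(m) - 1L
    res <- c(res, pos)
    from <- pos + 1L
  }
  res
}

# Exhaustive double-strand scan; returns hits in the package's 0-based
# half-open convention.
oracle_hits <- function(genome_chars, tags) {
  parts <- list()
  for (i in seq_len(nrow(tags))) {
    s <- tags$seq[i]
    rc <- oracle_rc(s)
    w <- nchar(s)
    for (chrom in names(genome_chars)) {
      fp <- oracle_find_all(genome_chars[[chrom]], s)
      rp <- oracle_find_all(genome_chars[[chrom]], rc)
      if (length(fp) + length(rp) == 0L) next
      parts[[length(parts) + 1L]] <- data.frame(
        tag_id = tags$tag_id[i], chrom = chrom,
        start = c(fp, rp) - 1L, end = c(fp, rp) - 1L + w,
        strand = rep(c("+", "-"), c(length(fp), length(rp))))
    }
  }
  if (!length(parts))
    return(data.frame(tag_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  do.call(rbind, parts)
}

canonical_hits <- function(h) {
  h <- h[, c("tag_id", "chrom", "start", "end", "strand")]
  h <- h[order(h$tag_id, h$chrom, h$start, h$strand, method = "radix"), ]
  rownames(h) <- NULL
  h
}

# ---- truth-table helpers -------------------------------------------------

# Map clean sequence -> ground-truth class, from an error-free simulation
# (inserts are then exact read prefixes). siRNA/other fold onto the
# pipeline's endo_siRNA/unannotated vocabulary.
truth_class_map <- function(sim) {
  ins <- substr(sim$reads$seq, 1, sim$truth$insert_len)
  cls <- sim$truth$class
  cls[cls == "siRNA"] <- "endo_siRNA"
  cls[cls == "other"] <- "unannotated"
  m <- tapply(cls, ins, function(x) paste(sort(unique(x)), collapse = ","))
  m
}

# Fraction of classified tags agreeing with the truth map (error-free sims
# should give exactly 1; ambiguous truth keys would show up as "a,b").
classification_accuracy <- function(classified, truth_map) {
  expected <- truth_map[classified$seq]
  mean(classified$class == expected)
}
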