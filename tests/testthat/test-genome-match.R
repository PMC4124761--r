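test_that("the index answers membership for every k-mer of a small genome", {
  g <- withr::with_seed(1, Biostrings::DNAStringSet(
    setNames(random_dna(1000L), "chr1")))
  idx <- build_index(g)
  gs <- as.character(g[[1]])
  starts <- seq(1, 1000 - 22 + 1, by = 7)
  kmers <- substring(gs, starts, starts + 21)
  tags <- data.frame(tag_id = paste0("k", seq_along(kmers)), seq = kmers,
                     count = 1L)
  hits <- match_tags(idx, tags)
  plus <- hits[hits$strand == "+", ]
  # every k-mer recovers at least its own source position
  found <- mapply(function(id, s0) any(plus$tag_id == id & plus$start == s0),
                  tags$tag_id, starts - 1L)
  expect_true(all(found))
})

test_that("an all-N genome never matches and an empty genome errors", {
  g <- Biostrings::DNAStringSet(setNames(strrep("N", 500), "chrN"))
  idx <- build_index(g)
  hits <- match_tags(idx, c(strrep("A", 20), "ACGTACGTACGTACGTACGT"))
  expect_equal(nrow(hits), 0L)
  expect_error(build_index(Biostrings::DNAStringSet()), "empty genome")
})

test_that("hit lists equal the independent double-strand scan oracle", {
  withr::with_seed(42, {
    for (rep in 1:3) {
      g <- setNames(random_dna(c(8000L, 5000L)), c("chr1", "chr2"))
      # half planted substrings (guaranteed hits), half random queries
      planted <- vapply(1:60, function(i) {
        chrom <- sample(names(g), 1)
        w <- sample(18:40, 1)
        s <- sample.int(nchar(g[[chrom]]) - w + 1L, 1)
        seq <- substr(g[[chrom]], s, s + w - 1L)
        if (runif(1) < 0.5) oracle_rc(seq) else seq
      }, character(1))
      rand <- random_dna(sample(18:40, 60, replace = TRUE))
      tags <- data.frame(tag_id = paste0("t", 1:120),
                         seq = c(planted, rand), count = 1L)
      idx <- build_index(Biostrings::DNAStringSet(g))
      expect_equal(canonical_hits(match_tags(idx, tags)),
                   canonical_hits(oracle_hits(g, tags)))
    }
  })
})

test_that("a reverse-complement palindrome yields hits on both strands", {
  pal <- "ACGTACGTACGCGTACGTACGT"
  expect_equal(oracle_rc(pal), pal)
  g <- withr::with_seed(3, setNames(
    paste0(random_dna(300L), pal, random_dna(300L)), "chr1"))
  idx <- build_index(Biostrings::DNAStringSet(g))
  hits <- match_tags(idx, pal)
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$strand, c("+", "-"))
  expect_equal(unique(hits$start), 300L)
  expect_equal(unique(hits$n_hits), 2L)
  expect_equal(canonical_hits(hits),
               canonical_hits(oracle_hits(
                 setNames(g, "chr1"),
                 data.frame(tag_id = "t1", seq = pal, count = 1L))))
})

test_that("matching is strand-symmetric", {
  withr::with_seed(9, {
    g <- setNames(random_dna(4000L), "chr1")
    w <- 24L
    s <- sample.int(4000L - w, 5)
    tags <- data.frame(tag_id = paste0("t", 1:5),
                       seq = substring(g, s, s + w - 1L), count = 1L)
    idx <- build_index(Biostrings::DNAStringSet(g))
    # a tag's reverse complement hits the same loci with strands flipped
    tags_rc <- transform(tags, seq = oracle_rc(seq))
    hf <- canonical_hits(match_tags(idx, tags))
    hr <- match_tags(idx, tags_rc)
    hr$strand <- ifelse(hr$strand == "+", "-", "+")
    expect_equal(hf, canonical_hits(hr))
    # and on the reverse-complemented genome, coordinates mirror
    idx_r <- build_index(Biostrings::DNAStringSet(setNames(oracle_rc(g),
                                                           "chr1")))
    hm <- match_tags(idx_r, tags)
    hm2 <- data.frame(tag_id = hm$tag_id, chrom = hm$chrom,
                      start = 4000L - hm$end, end = 4000L - hm$start,
                      strand = ifelse(hm$strand == "+", "-", "+"))
    expect_equal(hf, canonical_hits(hm2))
  })
})

test_that("every error-free simulated tag maps over its source locus", {
  run <- small_run()
  expect_setequal(unique(run$hits$tag_id), run$pp$tags$tag_id)
  # the truth locus appears among the hits of each read's tag
  tr <- run$sim$truth
  tr$seq <- substr(run$sim$reads$seq, 1, tr$insert_len)
  tr <- tr[tr$seq %in% run$pp$tags$seq, ]
  seq2tag <- setNames(run$pp$tags$tag_id, run$pp$tags$seq)
  all_loci <- suppressWarnings(c(
    run$bundle$annotation$mirna_mature, run$bundle$annotation$pirna,
    do.call(c, unname(run$bundle$annotation$structural)),
    run$bundle$repeats, run$bundle$other))
  ids <- S4Vectors::mcols(all_loci)$locus_id
  hgr <- GenomicRanges::GRanges(run$hits$chrom,
                                IRanges::IRanges(run$hits$start + 1L,
                                                 run$hits$end))
  check <- tr[!duplicated(paste(tr$seq, tr$locus_id)), ]
  ok <- vapply(seq_len(nrow(check)), function(i) {
    h <- which(run$hits$tag_id == seq2tag[[check$seq[i]]])
    loc <- all_loci[ids == check$locus_id[i]]
    any(IRanges::overlapsAny(hgr[h], loc, ignore.strand = TRUE))
  }, logical(1))
  expect_true(all(ok))
})

test_that("mapping summaries reproduce printed summary-table arithmetic", {
  expect_equal(mapping_summary(14223914, 10477211)$percentage, 73.66)
  expect_equal(mapping_summary(10648825, 8379103)$percentage, 78.69)
  expect_equal(mapping_summary(21086420, 17136082)$percentage, 81.27)
  expect_equal(mapping_summary(17791848, 13255304)$percentage, 74.50)
  expect_equal(mapping_summary(10740304, 8832696)$percentage, 82.24)
  expect_equal(mapping_summary(100, 100)$percentage, 100.00)
  expect_error(mapping_summary(0, 0), "undefined")
})

test_that("summarize_mapping counts reads of mapped tags", {
  tags <- data.frame(tag_id = c("a", "b", "c"),
                     seq = c(strrep("A", 20), strrep("C", 20),
                             strrep("G", 20)),
                     count = c(5L, 3L, 2L))
  hits <- data.frame(tag_id = c("a", "a", "c"), chrom = "chr1",
                     start = c(0L, 50L, 99L), end = c(20L, 70L, 119L),
                     strand = "+", n_hits = c(2L, 2L, 1L))
  m <- summarize_mapping(tags, hits)
  expect_equal(m$total_clean, 10L)
  expect_equal(m$mapped, 7L)
  expect_equal(m$percentage, 70.00)
})
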