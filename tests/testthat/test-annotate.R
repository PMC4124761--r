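# hand-built annotation fixture: one mature miRNA inside a hairpin, a tRNA
# locus, and a piRNA cluster that overlaps the miRNA (to probe priority).
fixture_ann <- function() {
  gr <- function(s, e, strand = "+", id, parent = NULL) {
    g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e), strand = strand)
    S4Vectors::mcols(g)$locus_id <- id
    if (!is.null(parent)) S4Vectors::mcols(g)$parent <- parent
    g
  }
  annotation_set(
    mirna_hairpin = gr(101, 180, "+", "mirA"),
    mirna_mature = gr(111, 132, "+", "mirA-5p", "mirA"),
    structural = list(tRNA = gr(301, 400, "+", "trna1")),
    pirna = gr(101, 1100, "+", "piX"))
}

fake_hits <- function(tag_id, start, end, strand = "+", n_hits = 1L) {
  data.frame(tag_id = tag_id, chrom = "chr1", start = start, end = end,
             strand = strand, n_hits = n_hits)
}

fake_tags <- function(tag_id, len, count = 1L) {
  withr::with_seed(1, data.frame(tag_id = tag_id,
                                 seq = random_dna(len), count = count))
}

test_that("miRNA outranks piRNA when a hit lies in both", {
  tags <- fake_tags("t1", 22L)
  hits <- fake_hits("t1", 110L, 132L)  # inside mature AND piRNA cluster
  cl <- classify_tags(tags, hits, fixture_ann())
  expect_equal(cl$class, "miRNA")
  expect_equal(cl$locus_id, "mirA-5p")
})

test_that("structural tier outranks piRNA, piRNA beats nothing else", {
  tags <- fake_tags(c("t1", "t2"), c(30L, 30L))
  hits <- rbind(fake_hits("t1", 320L, 350L),  # tRNA
                fake_hits("t2", 600L, 630L))  # piRNA cluster only
  cl <- classify_tags(tags, hits, fixture_ann())
  expect_equal(cl$class[cl$tag_id == "t1"], "tRNA")
  expect_equal(cl$class[cl$tag_id == "t2"], "piRNA")
})

test_that("a 30 nt tag with no track overlap stays unannotated", {
  tags <- fake_tags("t1", 30L)
  hits <- fake_hits("t1", 2000L, 2030L)
  cl <- classify_tags(tags, hits, fixture_ann())
  expect_equal(cl$class, "unannotated")
  expect_true(is.na(cl$locus_id))
})

test_that("the strand rule gates miRNA assignment", {
  tags <- fake_tags("t1", 22L)
  hits_minus <- fake_hits("t1", 110L, 132L, strand = "-")
  cl <- classify_tags(tags, hits_minus, fixture_ann())
  # wrong strand for the mature arm; the (same-strand-required) piRNA
  # cluster also fails, leaving the tag unannotated
  expect_equal(cl$class, "unannotated")
  cl2 <- classify_tags(tags, hits_minus, fixture_ann(),
                       pirna_stranded = FALSE)
  expect_equal(cl2$class, "piRNA")
})

test_that("partial overlaps below min_overlap_frac do not classify", {
  tags <- fake_tags("t1", 22L)
  # only 10 of 22 bases overlap the cluster start
  hits <- fake_hits("t1", 90L, 112L)
  cl <- classify_tags(tags, hits, fixture_ann(), min_overlap_frac = 0.8)
  expect_equal(cl$class, "unannotated")
  cl2 <- classify_tags(tags, hits, fixture_ann(), min_overlap_frac = 0.4)
  expect_equal(cl2$class, "miRNA")
})

test_that("annotation round-trips through GFF3 and BED", {
  b <- small_bundle()
  d <- withr::local_tempdir()
  paths <- write_genome_bundle(b, d)
  ann <- load_annotations(paths[["annotation"]])
  for (slot in c("mirna_hairpin", "mirna_mature", "pirna")) {
    expect_equal(GenomicRanges::start(ann[[slot]]),
                 GenomicRanges::start(b$annotation[[slot]]), info = slot)
    expect_equal(GenomicRanges::end(ann[[slot]]),
                 GenomicRanges::end(b$annotation[[slot]]), info = slot)
    expect_equal(S4Vectors::mcols(ann[[slot]])$locus_id,
                 S4Vectors::mcols(b$annotation[[slot]])$locus_id, info = slot)
    expect_equal(as.character(GenomicRanges::strand(ann[[slot]])),
                 as.character(GenomicRanges::strand(b$annotation[[slot]])),
                 info = slot)
  }
  reps <- load_repeats(paths[["repeats"]])
  expect_equal(length(reps), length(b$repeats))
  expect_setequal(unique(S4Vectors::mcols(reps)$family),
                  unique(S4Vectors::mcols(b$repeats)$family))
})

test_that("GFF3 1-based inclusive coordinates are honoured", {
  d <- withr::local_tempdir()
  gff <- file.path(d, "a.gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttoy\tpiRNA_cluster\t101\t122\t.\t+\t.\tID=p1"), gff)
  ann <- load_annotations(gff)
  expect_equal(GenomicRanges::start(ann$pirna), 101L)
  expect_equal(GenomicRanges::end(ann$pirna), 122L)
  # a hit at internal 0-based [100, 122) covers the locus exactly
  tags <- fake_tags("t1", 22L)
  cl <- classify_tags(tags, fake_hits("t1", 100L, 122L), ann)
  expect_equal(cl$class, "piRNA")
})

test_that("unknown annotation classes are rejected with the file named", {
  d <- withr::local_tempdir()
  gff <- file.path(d, "bad.gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttoy\tlncRNA\t1\t100\t.\t+\t.\tID=x1"), gff)
  expect_error(load_annotations(gff), "unknown annotation class.*lncRNA")
})

test_that("empty annotation leaves tags unannotated or endo-siRNA", {
  ann <- annotation_set()
  tags <- fake_tags(c("t1", "t2"), c(21L, 30L))
  hits <- rbind(fake_hits("t1", 500L, 521L), fake_hits("t2", 700L, 730L))
  reps <- GenomicRanges::GRanges("chr1", IRanges::IRanges(400, 900),
                                 family = "ERV1", locus_id = "r1")
  cl <- classify_tags(tags, hits, ann, reps)
  expect_equal(cl$class[cl$tag_id == "t1"], "endo_siRNA")  # 21 nt, repeat
  expect_equal(cl$class[cl$tag_id == "t2"], "unannotated") # 30 nt
})

test_that("simulated tags classify with full accuracy against the truth", {
  run <- small_run()
  acc <- classification_accuracy(run$classified, truth_class_map(run$sim))
  expect_equal(acc, 1)
})

test_that("priority is sound: no tag overlaps a higher class than its own", {
  run <- small_run()
  cl <- run$classified
  hits <- run$hits
  hgr <- GenomicRanges::GRanges(hits$chrom,
                                IRanges::IRanges(hits$start + 1L, hits$end),
                                strand = hits$strand)
  ann <- run$bundle$annotation
  mir_track <- suppressWarnings(c(GenomicRanges::granges(ann$mirna_hairpin),
                                  GenomicRanges::granges(ann$mirna_mature)))
  check_none <- function(tag_ids, track) {
    sel <- hits$tag_id %in% tag_ids
    if (!any(sel) || length(track) == 0) return(TRUE)
    ov <- GenomicRanges::findOverlaps(hgr[sel], track)
    if (!length(ov)) return(TRUE)
    w <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(hgr[sel])[S4Vectors::queryHits(ov)],
      GenomicRanges::ranges(track)[S4Vectors::subjectHits(ov)]))
    lens <- setNames(cl$length, cl$tag_id)
    all(w < 0.8 * lens[hits$tag_id[sel][S4Vectors::queryHits(ov)]])
  }
  pir_tags <- cl$tag_id[cl$class == "piRNA"]
  expect_true(check_none(pir_tags, mir_track))
  struct_tags <- cl$tag_id[cl$class %in% c("rRNA", "snoRNA", "tRNA",
                                           "scRNA", "snRNA")]
  expect_true(check_none(struct_tags, mir_track))
})

test_that("classification conserves reads and ignores input order", {
  run <- small_run()
  cl <- run$classified
  expect_equal(sum(cl$count),
               sum(run$pp$tags$count[run$pp$tags$tag_id %in%
                                       run$hits$tag_id]))
  perm <- withr::with_seed(2, sample(nrow(run$pp$tags)))
  cl2 <- classify_tags(run$pp$tags[perm, ], run$hits,
                       run$bundle$annotation, run$bundle$repeats)
  cl2 <- cl2[order(cl2$tag_id), ]
  cl1 <- cl[order(cl$tag_id), ]
  rownames(cl1) <- rownames(cl2) <- NULL
  expect_equal(cl1, cl2)
})

test_that("class composition fractions are exact arithmetic", {
  cl <- data.frame(tag_id = c("a", "b", "c"), seq = "x", count = c(600, 300, 100),
                   length = 22L, n_hits = 1L,
                   class = c("miRNA", "piRNA", "rRNA"),
                   locus_id = NA, chrom = NA, start = NA, strand = NA)
  comp <- class_composition(cl)
  expect_equal(setNames(comp$fraction, comp$class),
               c(miRNA = 0.6, piRNA = 0.3, rRNA = 0.1))
  one <- class_composition(cl[1, ])
  expect_equal(one$fraction, 1.0)
})

test_that("length distributions tabulate counts and normalise", {
  tags <- data.frame(seq = strrep("A", 22), count = 5L)
  ld <- length_distribution(tags)
  expect_equal(ld$reads[ld$length == 22], 5)
  expect_equal(sum(ld$reads), 5)
  expect_equal(sum(ld$density), 1)
})

test_that("dominant classes put the length peak where expected", {
  b <- small_bundle()
  idx <- build_index(b)
  peak_of <- function(mix, seed) {
    prof <- cell_profile("X", mix, seed = seed)
    s <- simulate_sample(b, prof, 6000)
    pp <- preprocess_reads(s$reads, prof$adapter3)
    hits <- match_tags(idx, pp$tags)
    cl <- classify_tags(pp$tags, hits, b$annotation, b$repeats)
    ld <- length_distribution(cl)
    ld$length[which.max(ld$reads)]
  }
  expect_true(peak_of(c(miRNA = 0.8, rRNA = 0.2), 31) %in% 22:23)
  expect_true(peak_of(c(piRNA = 0.8, rRNA = 0.2), 32) %in% 27:30)
})
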