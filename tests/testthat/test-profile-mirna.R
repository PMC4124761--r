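test_that("mature counting aggregates tag counts onto mature loci", {
  run <- small_run()
  cm <- count_mature(run$classified, run$hits, run$bundle$annotation)
  expect_true(all(cm$count > 0))
  # read conservation: miRNA-classified reads all land on matures (every
  # simulated miRNA read starts at a mature 5' end) — totals can only grow
  # if a tag hits two matures, never shrink
  expect_gte(sum(cm$count),
             sum(run$classified$count[run$classified$class == "miRNA"]))
  # no miRNA tags -> empty block
  none <- run$classified[run$classified$class == "piRNA", ]
  expect_equal(nrow(count_mature(none, run$hits, run$bundle$annotation)), 0L)
})

test_that("tags on one mature locus sum their counts", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 122),
                               strand = "+")
  S4Vectors::mcols(gr)$locus_id <- "mirA-5p"
  S4Vectors::mcols(gr)$parent <- "mirA"
  hp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(91, 170),
                               strand = "+")
  S4Vectors::mcols(hp)$locus_id <- "mirA"
  ann <- annotation_set(mirna_hairpin = hp, mirna_mature = gr)
  cl <- data.frame(tag_id = c("t1", "t2", "t3"), seq = strrep("A", 22),
                   count = c(5L, 2L, 1L), length = 22L, n_hits = 1L,
                   class = "miRNA", locus_id = "mirA-5p", chrom = "chr1",
                   start = 100L, strand = "+")
  hits <- data.frame(tag_id = c("t1", "t2", "t3"), chrom = "chr1",
                     start = 100L, end = 122L, strand = "+", n_hits = 1L)
  cm <- count_mature(cl, hits, ann)
  expect_equal(cm$count[cm$feature == "mirA-5p"], 8)
  # a hairpin-only tag lands in a flagged bucket
  hits2 <- rbind(hits, data.frame(tag_id = "t4", chrom = "chr1",
                                  start = 130L, end = 152L, strand = "+",
                                  n_hits = 1L))
  cl2 <- rbind(cl, data.frame(tag_id = "t4", seq = strrep("C", 22),
                              count = 3L, length = 22L, n_hits = 1L,
                              class = "miRNA", locus_id = "mirA",
                              chrom = "chr1", start = 130L, strand = "+"))
  cm2 <- count_mature(cl2, hits2, ann)
  expect_equal(cm2$count[cm2$feature == "hairpin:mirA"], 3)
  expect_equal(cm2$type[cm2$feature == "hairpin:mirA"], "hairpin")
})

test_that("RPM normalisation scales by library size and conserves 1e6", {
  raw <- matrix(c(100, 900, 0, 50, 150, 0), nrow = 3,
                dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  em <- rpm_normalize(raw, library_sizes = c(1e6, 1e6))
  expect_equal(em$rpm["a", "s1"], 100)
  expect_true(is.na(em$log2rpm["c", "s1"]))
  # under the per-sample total denominator every column sums to 1e6
  em2 <- rpm_normalize(raw)
  expect_equal(unname(colSums(em2$rpm)), c(1e6, 1e6))
  expect_error(rpm_normalize(raw, library_sizes = c(0, 1)), "positive")
})

test_that("expression calls use the RPM >= 1 boundary", {
  rpm <- matrix(c(1.0, 0.99, 0), ncol = 1,
                dimnames = list(c("a", "b", "c"), "s"))
  ex <- call_expressed(rpm)
  expect_true(ex["a", "s"])
  expect_false(ex["b", "s"])
  expect_false(ex["c", "s"])
})

sig_matrix <- function(f, others) {
  raw <- rbind(x = c(f, others))
  colnames(raw) <- c("focal", paste0("o", seq_along(others)))
  em <- rpm_normalize(raw, library_sizes = rep(1e6, length(others) + 1))
  em
}

test_that("signature boundary cases follow the exact 2-fold rule", {
  em <- sig_matrix(10, c(5, 5, 5, 5))
  expect_equal(call_signature(em, "focal")$feature, "x")
  em2 <- sig_matrix(10, c(5, 5, 6, 5))
  expect_equal(nrow(call_signature(em2, "focal")), 0L)
})

test_that("planted signatures are recovered exactly with no false positives", {
  withr::with_seed(101, {
    n <- 200; planted <- 1:20
    base <- matrix(runif(n * 4, 5, 200), nrow = n)
    focal <- apply(base, 1, max) * runif(n, 0.5, 1.2)
    focal[planted] <- apply(base[planted, ], 1, max) * runif(20, 4, 8)
    raw <- cbind(SSC = focal, ESC = base[, 1], GC = base[, 2],
                 ST = base[, 3], MSC = base[, 4])
    rownames(raw) <- paste0("m", 1:n)
    em <- rpm_normalize(raw, library_sizes = rep(1e6, 5))
    sig <- call_signature(em, "SSC", fold = 2)
    expect_setequal(sig$feature, paste0("m", planted))
    # the signature set shrinks (weakly) as the fold threshold rises
    sizes <- vapply(c(1.5, 2, 4),
                    function(f) nrow(call_signature(em, "SSC", fold = f)),
                    numeric(1))
    expect_true(all(diff(sizes) <= 0))
    # results are sorted by descending focal RPM
    expect_false(is.unsorted(rev(sig$focal_rpm)))
  })
})

test_that("signature calls are invariant to per-sample depth scaling", {
  withr::with_seed(7, {
    raw <- matrix(rpois(100 * 4, 40), nrow = 100,
                  dimnames = list(paste0("m", 1:100), c("A", "B", "C", "D")))
    em1 <- rpm_normalize(raw)
    raw2 <- raw; raw2[, "B"] <- raw2[, "B"] * 17
    em2 <- rpm_normalize(raw2)
    expect_equal(call_signature(em1, "A")$feature,
                 call_signature(em2, "A")$feature)
  })
})

test_that("signature calling validates its inputs", {
  em <- sig_matrix(10, c(5, 5))
  expect_error(call_signature(em, "nope"), "unknown focal")
  expect_error(call_signature(em, "focal", others = "focal"), "cannot be")
})

test_that("identical samples merge at height zero", {
  raw <- matrix(c(10, 20, 30, 10, 20, 30, 5, 80, 2), nrow = 3,
                dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  hc <- cluster_samples(rpm_normalize(raw, rep(1e6, 3)))
  expect_equal(min(hc$height), 0)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("s1", "s2"))
})

test_that("constructed geometry clusters pairs before the outlier", {
  withr::with_seed(33, {
    base1 <- runif(50, 1, 100); base2 <- runif(50, 1, 100)
    raw <- cbind(A = base1 * exp(rnorm(50, 0, 0.05)),
                 B = base1 * exp(rnorm(50, 0, 0.05)),
                 C = base2 * exp(rnorm(50, 0, 0.05)),
                 D = base2 * exp(rnorm(50, 0, 0.05)),
                 E = runif(50, 1, 100))
    rownames(raw) <- paste0("m", 1:50)
    hc <- cluster_samples(rpm_normalize(raw, rep(1e6, 5)))
    pairs <- lapply(1:2, function(i) {
      m <- hc$merge[i, ]
      if (all(m < 0)) sort(hc$labels[-m]) else NULL
    })
    expect_true(any(vapply(pairs, identical, logical(1), y = c("A", "B"))))
    expect_true(any(vapply(pairs, identical, logical(1), y = c("C", "D"))))
  })
})

test_that("simulated per-locus weights are recovered in mature counts", {
  b <- small_bundle()
  n_mat <- length(b$annotation$mirna_mature)
  w <- withr::with_seed(55, rgamma(n_mat, 1.5) + 0.05)
  prof <- cell_profile("X", c(miRNA = 1),
                       expression_weights = list(miRNA = w), seed = 56)
  s <- simulate_sample(b, prof, 20000)
  pp <- preprocess_reads(s$reads, prof$adapter3)
  idx <- build_index(b)
  hits <- match_tags(idx, pp$tags)
  cl <- classify_tags(pp$tags, hits, b$annotation, b$repeats)
  cm <- count_mature(cl, hits, b$annotation)
  ids <- S4Vectors::mcols(b$annotation$mirna_mature)$locus_id
  counts <- setNames(rep(0, n_mat), ids)
  counts[cm$feature[cm$type == "mature"]] <- cm$count[cm$type == "mature"]
  expect_gte(cor(w, counts, method = "spearman"), 0.9)
})
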