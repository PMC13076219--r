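test_that("bedGraph resampling is coverage-weighted and conserves signal
           on aligned boundaries", {
  f <- withr::local_tempfile(fileext = ".bg")
  writeLines(c("chr1\t0\t100\t2", "chr1\t100\t200\t4"), f)
  tr <- read_bedgraph(f, 50, c(chr1 = 200))
  expect_identical(tr$values$chr1, c(2, 2, 4, 4))
  expect_equal(sum(tr$values$chr1) * 50, 2 * 100 + 4 * 100)

  half <- withr::local_tempfile(fileext = ".bg")
  writeLines("chr1\t0\t75\t4", half)
  expect_identical(read_bedgraph(half, 50, c(chr1 = 100))$values$chr1,
                   c(4, 2))

  empty <- withr::local_tempfile(fileext = ".bg")
  writeLines(character(), empty)
  expect_identical(read_bedgraph(empty, 50, c(chr1 = 100))$values$chr1,
                   c(0, 0))
})

test_that("bedGraph rejects unsorted or overlapping records", {
  bad <- withr::local_tempfile(fileext = ".bg")
  writeLines(c("chr1\t100\t200\t1", "chr1\t0\t50\t1"), bad)
  expect_error(read_bedgraph(bad, 50, c(chr1 = 200)), "not sorted")
  ovl <- withr::local_tempfile(fileext = ".bg")
  writeLines(c("chr1\t0\t100\t1", "chr1\t50\t150\t1"), ovl)
  expect_error(read_bedgraph(ovl, 50, c(chr1 = 200)), "overlapping")
})

test_that("tracks round-trip through the bedGraph writer", {
  set.seed(5)
  tr <- one_chrom_track(rpois(40, 3))
  f <- withr::local_tempfile(fileext = ".bg")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, 50, c(chr1 = 2000))
  expect_equal(back$values$chr1, tr$values$chr1)
})

test_that("bin_coverage counts intervals fractionally and positions
           integrally, conserving totals", {
  asm <- c(chr1 = 200)
  bc <- bin_coverage(GRanges("chr1", IRanges(1, 100)), asm, 50)
  expect_identical(bc$values$chr1, c(1, 1, 0, 0))
  # conservation: sum(bins) * bin_size == total base overlap
  set.seed(8)
  st <- sample.int(150, 20, replace = TRUE)
  ivs <- GRanges("chr1", IRanges(st, st + sample.int(40, 20, TRUE)))
  bc2 <- bin_coverage(ivs, asm, 50)
  expect_equal(sum(bc2$values$chr1) * 50, sum(width(ivs)))
  # positions: one count per read start
  pos <- GRanges("chr1", IRanges(c(10, 60, 60), width = 1))
  bp <- bin_coverage(pos, asm, 50)
  expect_identical(bp$values$chr1, c(1, 2, 0, 0))
  expect_equal(sum(bp$values$chr1), length(pos))
  # RPM with a 1e6 library is the identity on raw counts
  rpm <- bin_coverage(GRanges("chr1", IRanges(1, 100)), asm, 50,
                      normalization = "RPM", total_units = 1e6)
  expect_identical(rpm$values$chr1, c(1, 1, 0, 0))
  expect_error(bin_coverage(GRanges(), asm, 50, normalization = "RPM"),
               "total_units")
  empty <- bin_coverage(GRanges(), asm, 50)
  expect_true(all(unlist(empty$values) == 0))
})

test_that("log2_ratio matches hand computation and is antisymmetric", {
  a <- one_chrom_track(c(21, 5, 0))
  b <- one_chrom_track(c(11, 5, 0))
  r <- log2_ratio(a, b, pseudocount = 11)
  expect_equal(r$values$chr1[1], log2(32 / 22))
  expect_equal(r$values$chr1[1], 0.5405684, tolerance = 1e-6)
  expect_identical(r$values$chr1[2:3], c(0, 0))
  r2 <- log2_ratio(b, a, pseudocount = 11)
  expect_equal(r$values$chr1, -r2$values$chr1)
  expect_true(all(log2_ratio(a, a, 11)$values$chr1 == 0))
  expect_error(log2_ratio(a, b, pseudocount = 0), "pseudocount")
})

test_that("signal_matrix equals a naive per-base double loop and handles
           strand orientation and chromosome edges", {
  set.seed(13)
  v <- rpois(200, 5)
  tr <- one_chrom_track(v, 50)            # chr1 length 10000
  n_anchor <- 50
  st <- sample.int(9000, n_anchor)
  anchors <- GRanges("chr1", IRanges(st, st + sample.int(500, n_anchor, TRUE)),
                     strand = sample(c("+", "-"), n_anchor, TRUE))
  flank <- 600; cb <- 100
  sm <- signal_matrix(tr, anchors, flank, cb, mode = "center")
  base_val <- function(p) ifelse(p >= 1 & p <= 10000, v[(p - 1) %/% 50 + 1], 0)
  naive <- matrix(0, n_anchor, 2 * flank / cb)
  for (i in seq_len(n_anchor)) {
    mid0 <- (start(anchors)[i] - 1 + end(anchors)[i]) %/% 2
    for (j in seq_len(ncol(naive))) {
      s0 <- mid0 - flank + (j - 1) * cb
      naive[i, j] <- mean(vapply((s0 + 1):(s0 + cb), base_val, numeric(1)))
    }
  }
  expect_equal(sm$matrix, naive, tolerance = 1e-9)
  expect_equal(sm$metaplot, colMeans(naive), tolerance = 1e-9)
  smo <- signal_matrix(tr, anchors, flank, cb, mode = "strand_oriented")
  neg <- as.character(strand(anchors)) == "-"
  expect_equal(smo$matrix[neg, ], naive[neg, ncol(naive):1])
  expect_equal(smo$matrix[!neg, ], naive[!neg, ])
})

test_that("fingerprint is a Lorenz curve: uniform tracks on the diagonal,
           focal tracks near zero, invariant to permutation and scale", {
  uni <- one_chrom_track(rep(3, 100))
  fu <- fingerprint(uni)
  expect_equal(fu$auc, 0.5, tolerance = 1 / 100)
  v <- rep(0, 100); v[17] <- 42
  ff <- fingerprint(one_chrom_track(v))
  expect_lt(ff$auc, 0.01)
  expect_true(all(ff$y <= ff$x + 1e-12))
  set.seed(3)
  w <- rgamma(100, 0.5)
  a1 <- fingerprint(one_chrom_track(w))$auc
  expect_equal(fingerprint(one_chrom_track(sample(w)))$auc, a1)
  expect_equal(fingerprint(one_chrom_track(7.3 * w))$auc, a1)
  expect_error(fingerprint(one_chrom_track(rep(0, 10))), "no positive")
})

test_that("sample_summary: duplicates correlate at 1, monotone transforms
           leave Spearman unchanged, planted groups separate on PC1", {
  set.seed(23)
  base <- rpois(400, 20)
  tA <- one_chrom_track(base, 50)
  tB <- one_chrom_track(base + rpois(400, 2), 50)
  ss <- sample_summary(list(tA, tA, tB), bin_size = 100, ntop = 100)
  expect_equal(ss$spearman[1, 2], 1)
  expect_true(isSymmetric(ss$spearman))
  expect_equal(diag(ss$spearman), rep(1, 3), ignore_attr = TRUE)
  # strictly monotone transform of one track leaves its Spearman row
  # unchanged (tracks built at the summary bin size, so no re-averaging
  # intervenes)
  tA2 <- one_chrom_track(base[1:200], 100)
  tB2 <- one_chrom_track(base[201:400], 100)
  tB2m <- one_chrom_track(exp(tB2$values$chr1 / 10), 100)
  ssA <- sample_summary(list(tA2, tB2), bin_size = 100, ntop = 100)
  ssB <- sample_summary(list(tA2, tB2m), bin_size = 100, ntop = 100)
  expect_equal(ssA$spearman[1, 2], ssB$spearman[1, 2], tolerance = 1e-12)
  # two planted condition groups separate along PC1 (sign-invariant)
  g1 <- lapply(1:3, function(i) one_chrom_track(base + rpois(400, 1), 50))
  g2 <- lapply(1:3, function(i) one_chrom_track(base + 50 + rpois(400, 1), 50))
  ss3 <- sample_summary(c(g1, g2), bin_size = 100, ntop = 100)
  pc1 <- ss3$pca_coords[, 1]
  expect_true(max(pc1[1:3]) < min(pc1[4:6]) ||
              min(pc1[1:3]) > max(pc1[4:6]))
  expect_error(sample_summary(list(tA)), "at least 2")
})

test_that("rebin_track averages constituent bins", {
  tr <- one_chrom_track(c(1, 3, 5, 7, 2, 4), 50)
  rb <- rebin_track(tr, 100)
  expect_identical(rb$values$chr1, c(2, 6, 3))
  expect_error(rebin_track(tr, 75), "multiple")
})

test_that("track_region_mean averages signal over intervals with flank", {
  tr <- one_chrom_track(c(2, 4, 6, 8), 50)  # chr1 length 200
  expect_equal(track_region_mean(tr, GRanges("chr1", IRanges(51, 100))), 4)
  expect_equal(track_region_mean(tr, GRanges("chr1", IRanges(51, 150))), 5)
  expect_equal(track_region_mean(tr, GRanges("chr1", IRanges(76, 125))), 5)
  # flank beyond the chromosome counts as zero signal
  expect_equal(track_region_mean(tr, GRanges("chr1", IRanges(1, 50)),
                                 flank = 50), (0 * 50 + 2 * 50 + 4 * 50) / 150)
})
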