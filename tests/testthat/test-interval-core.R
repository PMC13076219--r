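test_that("FASTA reading normalises case, maps U to T, and round-trips", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 description", "acgu", ">chr2", "NNACGT"), f)
  g <- read_fasta(f)
  expect_equal(as.character(g), c(chr1 = "ACGT", chr2 = "NNACGT"))
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g, f2)
  expect_equal(as.character(read_fasta(f2)), as.character(g))
  expect_equal(unname(Biostrings::width(g)), c(4L, 6L))
})

test_that("FASTA rejects duplicate names, empty records, bad characters", {
  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "AC", ">chr1", "GG"), dup)
  expect_error(read_fasta(dup), "duplicate")
  iupac <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGRT"), iupac)
  expect_error(read_fasta(iupac), "non-ACGTN")
})

test_that("BED dialects parse with 0-based half-open semantics", {
  b6 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100\tp1\t5\t+", b6)
  gr <- read_intervals(b6, "bed6")
  expect_equal(start(gr), 1L)
  expect_equal(end(gr), 100L)
  expect_equal(gr$name, "p1")
  expect_equal(as.character(strand(gr)), "+")

  b12 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t1000\t1200\tgA\t0\t+\t1000\t1200\t0\t2\t50,60\t0,140",
             b12)
  g12 <- read_intervals(b12, "bed12")
  ex <- g12$exons[[1]]
  expect_equal(start(ex), c(1001L, 1141L))
  expect_equal(end(ex), c(1050L, 1200L))
  expect_equal(g12$gene_id, "gA")

  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t10\t60\tpk\t900\t.\t5.5\t3.2\t2.1\t25", np)
  gnp <- read_intervals(np, "narrowPeak")
  expect_equal(width(gnp), 50L)
  expect_equal(gnp$signalValue, 5.5)
})

test_that("interval readers reject malformed rows with row context", {
  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10", "chr1\t100\t100"), empty)
  expect_error(read_intervals(empty, "bed3"), "row 2")
  neg <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t-5\t10", neg)
  expect_error(read_intervals(neg, "bed3"), "invalid interval")
})

test_that("BED round-trips through the companion writer", {
  gr <- GRanges("chr1", IRanges(c(1, 200), c(100, 250)),
                strand = c("+", "-"), name = c("a", "b"), score = c(1, 2))
  f <- withr::local_tempfile(fileext = ".bed")
  write_intervals(gr, f)
  back <- read_intervals(f, "bed6")
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_equal(back$name, gr$name)
  expect_equal(as.character(strand(back)), as.character(strand(gr)))
})

test_that("merge_intervals merges book-ended ranges and is idempotent", {
  gr <- GRanges("c", IRanges(c(1, 6, 11), c(10, 15, 20)))
  m <- merge_intervals(gr)
  expect_equal(length(m), 1L)
  expect_equal(c(start(m), end(m)), c(1L, 20L))
  disj <- GRanges("c", IRanges(c(1, 9), c(5, 9)))
  expect_equal(length(merge_intervals(disj)), 2L)

  set.seed(42)
  for (i in 1:10) {
    st <- sample.int(1000, 50, replace = TRUE)
    g <- GRanges("c", IRanges(st, st + sample.int(100, 50, replace = TRUE)))
    m1 <- merge_intervals(g)
    expect_identical(merge_intervals(m1), m1)
    expect_identical(merge_intervals(g[sample(50)]), m1)
    # base identity: union of covered positions preserved
    expect_equal(sum(width(m1)),
                 length(unique(unlist(Map(seq, start(g), end(g))))))
  }
})

test_that("window_overlap follows windowBed semantics", {
  a <- GRanges("c", IRanges(101, 200))
  expect_true(window_overlap(a, GRanges("c", IRanges(301, 400)), 150)$match)
  expect_false(window_overlap(a, GRanges("c", IRanges(201, 300)), 0)$match)
  expect_true(window_overlap(a, GRanges("c", IRanges(201, 300)), 1)$match)
  expect_true(window_overlap(a, GRanges("c", IRanges(150, 160)), 0)$match)
  # exact gap boundary: gap of `window` bp must NOT match
  expect_false(window_overlap(a, GRanges("c", IRanges(251, 300)), 50)$match)
  expect_true(window_overlap(a, GRanges("c", IRanges(251, 300)), 51)$match)
})

test_that("window_overlap equals the brute-force all-pairs gap oracle", {
  set.seed(7)
  for (w in c(0, 1, 37, 500)) {
    sa <- sample.int(5000, 80, replace = TRUE)
    sb <- sample.int(5000, 80, replace = TRUE)
    a <- GRanges(sample(c("c1", "c2"), 80, TRUE),
                 IRanges(sa, sa + sample.int(300, 80, TRUE)))
    b <- GRanges(sample(c("c1", "c2"), 80, TRUE),
                 IRanges(sb, sb + sample.int(300, 80, TRUE)))
    expect_identical(window_overlap(a, b, w)$match,
                     brute_window_match(a, b, w))
  }
})

test_that("genome coverage percent merges, bounds-checks, and is
           invariant to interval splitting", {
  asm <- c(chr1 = 1000)
  gr <- GRanges("chr1", IRanges(c(1, 51), c(100, 150)))
  expect_equal(genome_coverage_percent(gr, asm), 15)
  expect_equal(genome_coverage_percent(GRanges(), asm), 0)
  tiling <- GRanges("chr1", IRanges(seq(1, 901, 100), seq(100, 1000, 100)))
  expect_equal(genome_coverage_percent(tiling, asm), 100)
  expect_error(genome_coverage_percent(GRanges("chr1", IRanges(990, 1200)),
                                       asm), "beyond")
  split2 <- GRanges("chr1", IRanges(c(1, 40, 51), c(39, 100, 150)))
  expect_equal(genome_coverage_percent(split2, asm),
               genome_coverage_percent(gr, asm))
})

test_that("annotate_features assigns one category per peak by midpoint
           priority and the distribution partitions the peak set", {
  genes <- GRanges("chr1", IRanges(10000, 20000), strand = "+",
                   gene_id = "g1")
  ex <- GRangesList(GRanges("chr1", IRanges(c(10000, 15000),
                                            c(12000, 16000)), strand = "+"))
  mcols(genes)$exons <- ex
  peaks <- GRanges("chr1", IRanges(
    c(9000,   # 1 kb upstream of TSS -> promoter
      13000,  # inside gene, not exon, beyond TSS flank -> intron
      15100,  # inside second exon -> exon
      19900,  # near gene end -> TES
      40000), # gene-free -> intergenic
    width = 10))
  ann <- annotate_features(peaks, genes)
  expect_equal(as.character(ann$category),
               c("promoter", "intron", "exon", "TES", "intergenic"))
  expect_equal(sum(ann$distribution), length(peaks))
  expect_false(any(is.na(ann$category)))
})
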