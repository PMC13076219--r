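make_genes <- function(st, en, strand, id = NULL) {
  GRanges("chr1", IRanges(st, en), strand = strand,
          gene_id = if (is.null(id)) sprintf("g%02d", seq_along(st)) else id)
}

test_that("orient_rloops assigns by max overlap with deterministic
           tie-breaks and nearest-gene fallback", {
  genes <- make_genes(c(4801, 30000), c(20000, 40000), c("+", "-"))
  o <- orient_rloops(GRanges("chr1", IRanges(5001, 5500)), genes)
  expect_equal(o$txn_strand, "+")
  expect_equal(o$template_strand, "-")
  expect_equal(o$assignment, "overlap")
  # overlap 300 bp vs 450 bp: the larger overlap wins
  g2 <- make_genes(c(1000, 1751), c(1750, 3000), c("+", "-"))
  o2 <- orient_rloops(GRanges("chr1", IRanges(1451, 2200)), g2)
  expect_equal(o2$gene_id, "g02")
  # nearest within max_dist; unassigned beyond
  o3 <- orient_rloops(GRanges("chr1", IRanges(22001, 22200)), genes,
                      max_dist = 3000)
  expect_equal(o3$assignment, "nearest")
  expect_equal(o3$gene_id, "g01")
  o4 <- orient_rloops(GRanges("chr1", IRanges(24000, 24100)), genes,
                      max_dist = 3000)
  expect_equal(o4$assignment, "unassigned")
  expect_true(is.na(o4$txn_strand))
})

test_that("template/non-template assignment follows the exhaustive
           strand truth table", {
  for (gene_strand in c("+", "-")) {
    for (qps_strand in c("+", "-")) {
      genes <- make_genes(1000, 9000, gene_strand)
      rl <- orient_rloops(GRanges("chr1", IRanges(4000, 4500)), genes)
      g4 <- GRanges("chr1", IRanges(5000, 5100))
      qps <- GRanges("chr1", IRanges(5020, 5060), strand = qps_strand)
      sg <- assign_g4_strand(g4, qps, rl, window = 3000)
      expected <- if (gene_strand == qps_strand) "non_template"
                  else "template"
      expect_equal(sg$strand_class, expected,
                   label = paste("gene", gene_strand, "qps", qps_strand))
    }
  }
})

test_that("G4 peaks without QPS are dropped and both-strand QPS is
           flagged ambiguous", {
  genes <- make_genes(1000, 9000, "+")
  rl <- orient_rloops(GRanges("chr1", IRanges(4000, 4500)), genes)
  g4 <- GRanges("chr1", IRanges(c(5000, 6000), width = 100))
  qps <- GRanges("chr1", IRanges(c(5020, 5030), width = 40),
                 strand = c("+", "-"))
  sg <- assign_g4_strand(g4, qps, rl, window = 3000)
  expect_equal(length(sg), 1L)
  expect_equal(sg$strand_class, "ambiguous")
  expect_equal(attr(sg, "n_dropped_no_qps"), 1L)
})

test_that("colocalization profile is monotone in the window and errors
           on an empty R-loop set", {
  set.seed(37)
  st <- sample.int(1e6, 200)
  rl <- GRanges("chr1", IRanges(st, st + 500))
  sg <- sample.int(1e6, 60)
  g4 <- GRanges("chr1", IRanges(sg, sg + 100))
  pr <- colocalization_profile(rl, g4, windows = c(0, 1000, 3000, 10000))
  expect_true(all(diff(pr$fraction_with_g4) >= 0))
  expect_true(all(pr$fraction_with_g4 >= 0 & pr$fraction_with_g4 <= 1))
  inside <- GRanges("chr1", IRanges(st + 100, st + 150))
  expect_equal(colocalization_profile(rl, inside)$fraction_with_g4,
               rep(1, 4))
  expect_error(colocalization_profile(GRanges(), g4), "empty")
})

test_that("call_gloops categories partition assigned R-loops, with the
           documented sign convention and mirror symmetry", {
  genes <- make_genes(c(1000, 20000), c(9000, 29000), c("+", "-"))
  rl <- GRanges("chr1", IRanges(c(4000, 24000, 40000), c(4500, 24500, 40100)))
  o <- orient_rloops(rl, genes)
  # one non-template overlap, one template 2 kb upstream of the minus gene
  g4 <- GRanges("chr1", IRanges(c(4100, 26701), c(4200, 26800)))
  qps <- GRanges("chr1", IRanges(c(4120, 26720), width = 40),
                 strand = c("+", "+"))
  res <- call_gloops(o, g4, qps, window = 3000)
  expect_equal(res$calls$category, c("gloop_like", "template_g4"))
  expect_equal(res$calls$signed_distance[1], 0)
  expect_equal(res$calls$signed_distance[2], -2200L)
  expect_equal(res$summary$n_unassigned, 1L)
  expect_equal(sum(unlist(res$summary$counts)), res$summary$n_assigned)
  # mirror: flipping every strand leaves the category counts unchanged
  flip <- function(s) ifelse(s == "+", "-", "+")
  genes_m <- genes; strand(genes_m) <- flip(as.character(strand(genes)))
  qps_m <- qps; strand(qps_m) <- flip(as.character(strand(qps)))
  res_m <- call_gloops(orient_rloops(rl, genes_m), g4, qps_m, window = 3000)
  expect_equal(res_m$summary$counts, res$summary$counts)
})

test_that("call_gloops recovers a planted split on a spaced cohort", {
  co <- simulate_gloop_cohort(n = 150, seed = 41)
  qps <- g4hunter_call(co$genome)
  o <- orient_rloops(co$rloops, co$genes)
  gl <- call_gloops(o, co$g4_peaks, qps, window = 3000)
  expect_equal(gl$calls$category, co$truth$category)
  expect_equal(gl$summary$nontemplate_share,
               sum(co$truth$category == "gloop_like") /
                 sum(co$truth$category != "no_g4"))
})

test_that("resolution classification applies the a > b > c > other
           precedence and theta monotonicity", {
  asm <- c(chr1 = 100000)
  rl <- GRanges("chr1", IRanges(c(1000, 11000, 21000, 31000), width = 500))
  lost <- GRanges("chr1", IRanges(c(1000, 11000), width = 500))
  bound <- GRanges("chr1", IRanges(c(21000, 31000), width = 500))
  rpa <- GRanges("chr1", IRanges(c(11000, 21000, 31000), width = 500))
  nb <- ceiling(100000 / 50)
  v <- rep(-0.5, nb)
  hyp_bins <- function(gr) (start(gr) - 1) %/% 50 + seq_len(500 / 50)
  v[hyp_bins(rl[2])] <- 1; v[hyp_bins(rl[3])] <- 1
  prate <- binned_track(list(chr1 = v), 50, asm)
  res <- classify_resolution(rl, bound, lost, rpa, prate)
  expect_equal(as.character(res$calls$category),
               c("a_lost_rpa_depleted", "b_lost_hyperphos",
                 "c_bound_hyperphos", "other"))
  expect_equal(sum(res$frequencies), 1)
  # raising theta can only shrink the hyperphosphorylated categories
  bc <- vapply(c(-1, 0, 0.5, 2), function(th) {
    fr <- classify_resolution(rl, bound, lost, rpa, prate,
                              theta = th)$frequencies
    fr[["b_lost_hyperphos"]] + fr[["c_bound_hyperphos"]]
  }, numeric(1))
  expect_true(all(diff(bc) <= 0))
})

test_that("planted resolution categories are recovered on a spaced
           cohort", {
  sim <- simulate_resolution_cohort(n = 300, seed = 43)
  res <- classify_resolution(sim$rloops, sim$rnh1_peaks, sim$rnh1_lost,
                             sim$rpa32_peaks, sim$prate)
  planted <- table(factor(sim$truth$category,
                          levels = names(res$frequencies))) / 300
  expect_true(all(abs(res$frequencies - as.numeric(planted)) <= 0.03))
})
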