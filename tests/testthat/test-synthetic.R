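small_cfg <- function(seed = 1)
  sim_config(seed = seed,
             chrom_sizes = c(chr1 = 400000, chr2 = 150000),
             n_genes = 25, gene_len_range = c(2000, 8000),
             n_rloops = 60, pausing_bins = 2)

test_that("genome and gene simulation is deterministic under the seed
           and honours its constraints", {
  g1 <- simulate_genome_and_genes(small_cfg(5))
  g2 <- simulate_genome_and_genes(small_cfg(5))
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(start(g1$genes), start(g2$genes))
  g3 <- simulate_genome_and_genes(small_cfg(6))
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))
  # genes non-overlapping, stranded, within bounds
  expect_equal(length(g1$genes), 25L)
  expect_true(all(as.character(strand(g1$genes)) %in% c("+", "-")))
  expect_equal(length(GenomicRanges::reduce(g1$genes, ignore.strand = TRUE)),
               length(GenomicRanges::reduce(g1$genes, ignore.strand = TRUE,
                                            min.gapwidth = 0L)))
  expect_true(all(width(g1$genes) >= 2000 & width(g1$genes) <= 8001))
  # exons sorted, non-overlapping, inside the gene
  for (i in seq_len(5)) {
    ex <- g1$genes$exons[[i]]
    expect_true(all(start(ex) >= start(g1$genes)[i]))
    expect_true(all(end(ex) <= end(g1$genes)[i]))
    expect_true(all(diff(start(ex)) > 0))
  }
  # GC within 3 binomial SDs of the configured 0.5
  freq <- Biostrings::alphabetFrequency(g1$genome, collapse = TRUE)
  n <- sum(freq[c("A", "C", "G", "T")])
  gc <- sum(freq[c("C", "G")]) / n
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / n))
  # empty annotation is allowed
  g0 <- simulate_genome_and_genes(sim_config(
    seed = 2, chrom_sizes = c(chr1 = 50000), n_genes = 0))
  expect_equal(length(g0$genes), 0L)
})

test_that("planted QPS motifs always clear the verification margin on
           the requested strand", {
  set.seed(55)
  genome <- DNAStringSet(c(chr1 = random_dna_string(40000)))
  sites <- GRanges("chr1", IRanges(seq(1000, 39000, by = 2000), width = 1),
                   strand = rep(c("+", "-"), 10))
  pl <- plant_qps(genome, sites, margin = 1.3)
  expect_equal(length(pl$truth), 20L)
  ws <- g4hunter_window_scores(as.character(pl$genome[["chr1"]]))
  for (i in seq_along(pl$truth)) {
    lo <- max(1, start(pl$truth)[i] - 24)
    w <- ws[lo:min(end(pl$truth)[i], length(ws))]
    if (as.character(strand(pl$truth))[i] == "+")
      expect_gte(max(w), 1.3)
    else expect_lte(min(w), -1.3)
  }
})

test_that("the gloop cohort plants exact category counts with clean
           geometry", {
  co <- simulate_gloop_cohort(n = 100, gloop_fraction = 0.79,
                              template_fraction = 0.21, seed = 57)
  expect_equal(sum(co$truth$category == "gloop_like"), 79L)
  expect_equal(sum(co$truth$category == "template_g4"), 21L)
  expect_equal(length(co$g4_peaks), 100L)
  # every planted G4 peak is within the calling window of its R-loop
  expect_true(all(window_overlap(co$rloops, co$g4_peaks, 3000)$match))
  co2 <- simulate_gloop_cohort(n = 100, seed = 57)
  expect_identical(as.character(co$genome), as.character(co2$genome))
})

test_that("the colocalization cohort plants exact window fractions", {
  co <- simulate_coloc_cohort(n = 200, frac3 = 0.6, frac10 = 0.85,
                              seed = 59)
  pr <- colocalization_profile(co$rloops, co$g4_peaks,
                               windows = c(3000, 10000))
  expect_equal(pr$fraction_with_g4, c(0.6, 0.85))
})

test_that("the resolution cohort separates planted hyperphosphorylation
           on the rate track", {
  sim <- simulate_resolution_cohort(n = 200, seed = 61)
  m <- track_region_mean(sim$prate, sim$rloops)
  hyper <- sim$truth$category %in% c("b_lost_hyperphos",
                                     "c_bound_hyperphos")
  # strong separation in the mean rate between planted groups
  expect_gt(min(m[hyper]), 0)
  expect_lt(mean(m[!hyper] > 0), 0.05)
})

test_that("trael simulation responds to its knobs and keeps truth
           aligned with the tracks", {
  sim <- simulate_trael(n_bins = 480, mu = 50, pausing_fraction = 0.05,
                        seed = 63)
  expect_equal(length(sim$truth), 24L)
  tot0 <- sum(unlist(sim$day0$values))
  expect_equal(tot0, 480 * 50, tolerance = 0.1)
  # planted bins have elevated day3 counts on average
  d3 <- unlist(sim$day3$values)
  pausing_mask <- overlapsAny(
    GRanges(rep(names(sim$day0$values), each = 20),
            IRanges(rep((0:19) * 50000 + 1, 24), width = 50000)),
    sim$truth)
  expect_gt(mean(d3[pausing_mask]), 1.7 * mean(d3[!pausing_mask]))
  # library scaling leaves planted truth identical
  simx <- simulate_trael(n_bins = 480, lib_factor = 3, seed = 63)
  expect_equal(granges(simx$truth), granges(sim$truth))
})

test_that("FP titration simulation is exact at zero noise and seeded", {
  s0 <- simulate_fp(noise_sd = 0, seed = 65)
  expect_equal(s0$data$FP,
               isotherm_value(s0$data$P_T, 150e-9, 50, 300, 30e-9))
  s1 <- simulate_fp(noise_sd = 0.01, seed = 65)
  s2 <- simulate_fp(noise_sd = 0.01, seed = 65)
  expect_identical(s1$data$FP, s2$data$FP)
})

test_that("bundle truth counts are recoverable from the emitted files", {
  cfg <- small_cfg(7)
  b <- simulate_peaks_and_tracks(cfg)
  out <- withr::local_tempdir()
  write_bundle(b, out)
  rl <- read_intervals(file.path(out, "rloops_cond1.bed"), "bed3")
  expect_equal(length(rl), length(b$rloops_cond1))
  expect_equal(start(rl), start(b$rloops_cond1))
  genes <- read_intervals(file.path(out, "genes.bed12"), "bed12")
  expect_equal(length(genes), length(b$genes))
  truth <- jsonlite::read_json(file.path(out, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(length(truth$gloop_category), length(b$rloops_cond1))
  expect_equal(truth$seed, cfg$seed)
  asm <- read_chrom_sizes(file.path(out, "chrom.sizes"))
  expect_equal(seqlengths(asm), seqlengths(b$assembly))
  fa <- read_fasta(file.path(out, "genome.fa"))
  expect_identical(as.character(fa), as.character(b$genome))
})
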