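#' Simulation configuration
#'
#' Defaults define the study conditions the generators emulate: a small
#' two-chromosome genome (1.5 Mb + 0.5 Mb), 80 non-overlapping genes,
#' 500 R-loops per condition anchored near gene TSSs, a 79% / 21%
#' non-template / template split of planted QPS configurations, 50 bp
#' signal bins with Poisson counts at baseline rate 2 per bin, and a
#' fluorescence polarization titration of a 30 nM probe over
#' 0.03--30 uM protein with K_D 150 nM.
#'
#' @param seed Master seed; per-component substreams are derived from it
#'   by fixed offsets, so adding one component does not shift the others.
#' @param chrom_sizes Named chromosome lengths (bp).
#' @param n_genes Number of non-overlapping genes.
#' @param gene_len_range Gene length bounds (bp).
#' @param gc Background GC content.
#' @param n_rloops R-loops per condition.
#' @param rloop_width_range R-loop peak width bounds (bp).
#' @param cond1_specific_fraction Share of each condition's R-loops that
#'   is condition-specific (the rest are shared).
#' @param gloop_fraction,template_fraction Planted shares of R-loops with
#'   a non-template-strand QPS within `gloop_window`, resp. a
#'   template-strand QPS upstream; the remainder gets no QPS.
#' @param gloop_window G-loop calling window emulated by planting (bp).
#' @param track_bin Signal track bin size (bp).
#' @param lambda0 Baseline Poisson rate (counts/bin).
#' @param enrichment Multiplier applied inside peaks/domains.
#' @param prpa_baseline,prpa_hyper Phospho-RPA32 rate multipliers outside /
#'   inside hyperphosphorylated R-loops (relative to total RPA32).
#' @param resolution_freqs Planted fractions of R-loop resolution-failure
#'   categories a (RNase H1 lost, RPA32 depleted), b (lost,
#'   hyperphosphorylated) and c (bound, hyperphosphorylated); the
#'   remainder is "other". Defaults follow the reported genome-wide
#'   frequencies (8.3%, 5.2%, 43.1%).
#' @param pausing_bins Number of planted fork-pausing 50 kb bins in the
#'   bundle's read-start tracks.
#' @param fp List: `K_D`, `L_T` (molar), `F_L`, `F_LP` (polarization
#'   units), `noise_sd` (multiplicative), `grid` (protein molarities).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chrom_sizes = c(chr1 = 1500000, chr2 = 500000),
                       n_genes = 80,
                       gene_len_range = c(2000, 20000),
                       gc = 0.5,
                       n_rloops = 500,
                       rloop_width_range = c(200, 2000),
                       cond1_specific_fraction = 0.4,
                       gloop_fraction = 0.79,
                       template_fraction = 0.21,
                       gloop_window = 3000,
                       track_bin = 50,
                       lambda0 = 2,
                       enrichment = 5,
                       prpa_baseline = 0.5,
                       prpa_hyper = 3,
                       resolution_freqs = c(a = 0.083, b = 0.052,
                                            c = 0.431),
                       pausing_bins = 4,
                       fp = list(K_D = 150e-9, L_T = 30e-9, F_L = 50,
                                 F_LP = 300, noise_sd = 0.01,
                                 grid = NULL)) {
  stopifnot(gloop_fraction >= 0, template_fraction >= 0,
            gloop_fraction + template_fraction <= 1,
            lambda0 > 0, track_bin >= 1)
  if (is.null(fp$grid))
    fp$grid <- exp(seq(log(0.03e-6), log(30e-6), length.out = 12))
  structure(as.list(environment()), class = "sim_config")
}

# Independent substream k of the master seed (kept below 2^31).
.set_substream <- function(seed, k) {
  set.seed((as.integer(seed) %% 1000003L) * 1009L + 7919L * k)
}

.random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a genome and non-overlapping gene models
#'
#' Background sequence is i.i.d. over ACGT at the configured GC content;
#' genes are placed without overlap (uniform lengths within
#' `gene_len_range`, strands Bernoulli(0.5)) and given a simple
#' exon/intron structure (alternating blocks). Deterministic under the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (`DNAStringSet`), `genes` (`GRanges` with
#'   `gene_id` and `exons` columns), `assembly` (`Seqinfo`).
#' @export
simulate_genome_and_genes <- function(config = sim_config()) {
  .set_substream(config$seed, 1L)
  genome <- Biostrings::DNAStringSet(vapply(
    config$chrom_sizes, .random_dna, character(1), gc = config$gc))
  names(genome) <- names(config$chrom_sizes)
  si <- as_assembly(config$chrom_sizes)

  genes <- GRanges()
  if (config$n_genes > 0) {
    sizes <- config$chrom_sizes
    weights <- sizes / sum(sizes)
    kept <- stats::setNames(
      rep(list(list(st = integer(), en = integer())), length(sizes)),
      names(sizes))
    n_kept <- 0L
    chv <- character(config$n_genes)
    stv <- integer(config$n_genes)
    env <- integer(config$n_genes)
    tries <- 0L
    while (n_kept < config$n_genes) {
      tries <- tries + 1L
      if (tries > 1000L * config$n_genes)
        stop("could not place ", config$n_genes, " non-overlapping genes; ",
             "reduce n_genes or gene lengths")
      ch <- sample(names(sizes), 1, prob = weights)
      len <- round(stats::runif(1, config$gene_len_range[1],
                                config$gene_len_range[2]))
      if (len + 2 > sizes[[ch]]) next
      st <- sample.int(sizes[[ch]] - len, 1)
      en <- st + len - 1L
      k <- kept[[ch]]
      if (length(k$st) && any(st <= k$en & en >= k$st)) next
      kept[[ch]]$st <- c(k$st, st)
      kept[[ch]]$en <- c(k$en, en)
      n_kept <- n_kept + 1L
      chv[n_kept] <- ch; stv[n_kept] <- st; env[n_kept] <- en
    }
    genes <- sort(GRanges(chv, IRanges(stv, env),
                          strand = sample(c("+", "-"), config$n_genes,
                                          replace = TRUE)),
                  ignore.strand = TRUE)
    mcols(genes)$gene_id <- sprintf("gene%04d", seq_along(genes))
    # alternating exon/intron blocks: 2-6 exons per gene
    exons <- GenomicRanges::GRangesList(lapply(seq_along(genes), function(i) {
      g <- genes[i]
      n_ex <- sample(2:6, 1)
      cuts <- sort(sample.int(width(g) - 1L, 2L * n_ex - 2L))
      bounds <- c(0L, cuts, width(g))
      st <- bounds[seq(1, length(bounds) - 1, by = 2)]
      en <- bounds[seq(2, length(bounds), by = 2)]
      GRanges(GenomeInfoDb::seqnames(g),
              IRanges(start(g) + st, start(g) + en - 1L),
              strand = strand(g))
    }))
    mcols(genes)$exons <- exons
  }
  genes <- .set_assembly(genes, si)
  list(genome = genome, genes = genes, assembly = si)
}

# One QPS motif: four G4 tracts joined by 1-7 nt A/T loops (no C/G in
# loops, so the G4Hunter score is not diluted or extended).
.qps_motif <- function() {
  loops <- vapply(1:3, function(i)
    paste(sample(c("A", "T"), sample(1:7, 1), replace = TRUE),
          collapse = ""), character(1))
  paste0("GGGG", loops[1], "GGGG", loops[2], "GGGG", loops[3], "GGGG")
}

# Max same-sign G4Hunter window mean over a local stretch of the genome.
.local_g4_score <- function(genome, ch, st, en, window = 25) {
  L <- Biostrings::width(genome[ch])
  lo <- max(1L, st - window + 1L)
  hi <- min(L, en + window - 1L)
  s <- g4hunter_base_scores(as.character(subseq(genome[[ch]], lo, hi)))
  n <- length(s)
  if (n < window) return(c(0, 0))
  cs <- c(0, cumsum(s))
  wm <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  c(max(wm), min(wm))
}

#' Plant QPS motifs into a genome with verified G4Hunter scores
#'
#' Writes `(GGGG loop){3} GGGG` motifs (loops 1-7 nt of A/T) at the given
#' positions and strands. To make the planted strand evidence unambiguous,
#' the `scrub_flank` bp flanking each motif are replaced with random A/T
#' (so no background G- or C-run can create an overlapping opposite-strand
#' window at the planted site). Every planted site is then verified to
#' reach a G4Hunter window mean of at least `margin` (default 1.3, above
#' the 1.2 calling threshold, so recall is guaranteed by construction),
#' resampling loops up to 20 times otherwise.
#'
#' @param genome `DNAStringSet`.
#' @param sites `GRanges` (width-1 anchor: motif start) with strand
#'   `+`/`-`.
#' @param margin Required |window mean| at window 25.
#' @param scrub_flank Flank width neutralised to A/T around each motif
#'   (bp); 126 covers the maximum G4-peak jitter (100) plus one window.
#' @return List with `genome` (modified), `truth` (`GRanges` of the
#'   planted motifs, stranded) and `planted` (logical per requested site;
#'   sites whose motifs would overlap an earlier one are skipped).
#' @export
plant_qps <- function(genome, sites, margin = 1.3, scrub_flank = 126L) {
  if (length(sites) == 0) return(list(genome = genome, truth = GRanges()))
  chs <- as.character(GenomeInfoDb::seqnames(sites))
  strs <- as.character(strand(sites))
  if (any(!strs %in% c("+", "-"))) stop("sites must be stranded (+/-)")
  motifs <- vapply(seq_along(sites), function(i) {
    m <- .qps_motif()
    if (strs[i] == "-")
      m <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(m)))
    m
  }, character(1))
  st <- start(sites)
  en <- st + nchar(motifs) - 1L
  # overlapping requests cannot all be written; keep a greedy
  # left-to-right non-overlapping subset per chromosome
  keep <- rep(TRUE, length(sites))
  for (ch in unique(chs)) {
    i <- which(chs == ch)
    ord <- i[order(st[i])]
    last_en <- -1L
    for (j in ord) {
      if (st[j] <= last_en) keep[j] <- FALSE else last_en <- en[j]
    }
  }
  if (!all(keep)) {
    sites <- sites[keep]; chs <- chs[keep]; strs <- strs[keep]
    motifs <- motifs[keep]; st <- st[keep]; en <- en[keep]
  }
  for (ch in unique(chs)) {
    L <- Biostrings::width(genome[ch])
    i <- which(chs == ch)
    if (any(en[i] + scrub_flank > L) || any(st[i] - scrub_flank < 1L))
      stop("motif flank at ", ch, ":", st[i][1],
           " extends beyond the chromosome")
    # pass 1: neutralise flanks (merged, so ranges stay disjoint)
    scrub <- IRanges::reduce(IRanges(st[i] - scrub_flank,
                                     en[i] + scrub_flank))
    at_txt <- vapply(width(scrub), function(wd)
      paste(sample(c("A", "T"), wd, replace = TRUE), collapse = ""),
      character(1))
    genome[[ch]] <- Biostrings::replaceAt(genome[[ch]], scrub,
                                          Biostrings::DNAStringSet(at_txt))
    # pass 2: write the motifs
    ord <- order(st[i])
    genome[[ch]] <- Biostrings::replaceAt(
      genome[[ch]], IRanges(st[i][ord], en[i][ord]),
      Biostrings::DNAStringSet(motifs[i][ord]))
  }
  for (i in seq_along(sites)) {
    for (try in 1:20) {
      sc <- .local_g4_score(genome, chs[i], st[i], en[i])
      ok <- if (strs[i] == "+") sc[1] >= margin else sc[2] <= -margin
      if (ok) break
      if (try == 20) stop("QPS verification failed at ", chs[i], ":", st[i])
      # resample loops, keeping the motif length so coordinates stand
      repeat {
        m <- .qps_motif()
        if (nchar(m) == nchar(motifs[i])) break
      }
      if (strs[i] == "-")
        m <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(m)))
      genome[[chs[i]]] <- Biostrings::replaceAt(
        genome[[chs[i]]], IRanges(st[i], en[i]),
        Biostrings::DNAStringSet(m))
      motifs[i] <- m
    }
  }
  truth <- sort(GRanges(chs, IRanges(st, en), strand = strs),
                ignore.strand = TRUE)
  list(genome = genome, truth = truth, planted = keep)
}

#' Planted-geometry cohort for G-loop split recovery
#'
#' Builds one synthetic locus ("territory") per R-loop, spaced so that no
#' planted QPS of one territory falls within the calling window of
#' another. Each territory carries one gene (random strand), one R-loop
#' downstream of the TSS, and -- per the planted category -- a QPS motif
#' on the non-template strand within `window` (gloop-like), on the
#' template strand upstream (template), or none. G4 "peaks" are the
#' planted motifs expanded by up to 100 bp of jitter. Category counts are
#' planted exactly (`floor(n * fraction)`).
#'
#' @param n Number of R-loops.
#' @param gloop_fraction,template_fraction Planted category shares.
#' @param window Calling window the geometry respects (bp).
#' @param seed Seed.
#' @return List with `genome`, `assembly`, `genes`, `rloops`, `g4_peaks`,
#'   `qps_truth`, `truth` (data.frame with per-R-loop `category`).
#' @export
simulate_gloop_cohort <- function(n = 1000, gloop_fraction = 0.79,
                                  template_fraction = 0.21,
                                  window = 3000, seed = 1) {
  stopifnot(gloop_fraction + template_fraction <= 1)
  .set_substream(seed, 2L)
  T_ <- 16000L
  L <- n * T_ + T_
  n_g <- floor(n * gloop_fraction)
  n_t <- floor(n * template_fraction)
  category <- sample(c(rep("gloop_like", n_g), rep("template_g4", n_t),
                       rep("no_g4", n - n_g - n_t)))
  base <- (seq_len(n) - 1L) * T_
  gene_st <- base + 2000L
  gene_en <- base + 10000L
  str <- sample(c("+", "-"), n, replace = TRUE)
  w <- round(stats::runif(n, 300, 1500))
  o <- round(stats::runif(n, 500, 2000))  # R-loop offset from TSS
  rl_st <- ifelse(str == "+", gene_st + o, gene_en - o - w + 1L)
  rl_en <- rl_st + w - 1L

  plant <- category != "no_g4"
  gap <- ifelse(category == "gloop_like",
                round(stats::runif(n, 0, 2000)),
                round(stats::runif(n, 200, 2000)))
  motif_len_max <- 37L
  # gloop-like: downstream of the R-loop in txn coords, QPS on txn strand;
  # template: upstream, QPS on the opposite strand.
  down <- (category == "gloop_like") == (str == "+")
  m_st <- ifelse(down, rl_en + gap + 1L, rl_st - gap - motif_len_max)
  qps_strand <- ifelse(category == "gloop_like", str,
                       ifelse(str == "+", "-", "+"))

  genome <- Biostrings::DNAStringSet(c(chr1 = .random_dna(L)))
  sites <- GRanges("chr1", IRanges(m_st[plant], width = 1L),
                   strand = qps_strand[plant])
  pl <- plant_qps(genome, sites)
  genome <- pl$genome
  qps_truth <- pl$truth

  j1 <- sample.int(101L, sum(plant), replace = TRUE) - 1L
  j2 <- sample.int(101L, sum(plant), replace = TRUE) - 1L
  g4_peaks <- GRanges("chr1", IRanges(pmax(start(pl$truth) - j1, 1L),
                                      pmin(end(pl$truth) + j2, L)))
  si <- as_assembly(c(chr1 = L))
  genes <- GRanges("chr1", IRanges(gene_st, gene_en), strand = str,
                   gene_id = sprintf("gene%05d", seq_len(n)))
  rloops <- GRanges("chr1", IRanges(rl_st, rl_en))
  genes <- .set_assembly(genes, si)
  rloops <- .set_assembly(rloops, si)
  g4_peaks <- .set_assembly(g4_peaks, si)
  list(genome = genome, assembly = si, genes = genes, rloops = rloops,
       g4_peaks = g4_peaks, qps_truth = qps_truth,
       truth = data.frame(category = category, txn_strand = str,
                          stringsAsFactors = FALSE))
}

#' Planted-geometry cohort for the colocalization profile
#'
#' Interval-only generator: R-loops and G4 peaks are placed in spaced
#' territories so that exactly `frac3` of R-loops have a G4 within 3 kb,
#' `frac10` within 10 kb, and the rest none within 10 kb.
#'
#' @param n Number of R-loops.
#' @param frac3,frac10 Planted cumulative fractions at 3 kb and 10 kb.
#' @param seed Seed.
#' @return List with `rloops`, `g4_peaks` (`GRanges`), `assembly`,
#'   `truth` (data.frame with planted class per R-loop).
#' @export
simulate_coloc_cohort <- function(n = 500, frac3 = 0.60, frac10 = 0.85,
                                  seed = 1) {
  stopifnot(frac3 <= frac10, frac10 <= 1)
  .set_substream(seed, 3L)
  T_ <- 24000L
  n3 <- floor(n * frac3)
  n10 <- floor(n * frac10) - n3
  cls <- sample(c(rep("within3k", n3), rep("within10k", n10),
                  rep("none", n - n3 - n10)))
  base <- (seq_len(n) - 1L) * T_
  w <- round(stats::runif(n, 200, 2000))
  rl_st <- base + 2000L
  rl_en <- rl_st + w - 1L
  g4_w <- round(stats::runif(n, 100, 300))
  gap <- ifelse(cls == "within3k", round(stats::runif(n, 0, 2500)),
                round(stats::runif(n, 3200, 9500)))
  g4_st <- rl_en + gap + 1L
  keep <- cls != "none"
  si <- as_assembly(c(chr1 = n * T_ + T_))
  rloops <- GRanges("chr1", IRanges(rl_st, rl_en))
  g4_peaks <- GRanges("chr1", IRanges(g4_st[keep],
                                      g4_st[keep] + g4_w[keep] - 1L))
  rloops <- .set_assembly(rloops, si)
  g4_peaks <- .set_assembly(g4_peaks, si)
  list(rloops = rloops, g4_peaks = g4_peaks, assembly = si,
       truth = data.frame(class = cls, stringsAsFactors = FALSE))
}

#' Planted cohort for resolution-failure classification
#'
#' Plants R-loops of four categories at exact counts: (a) RNase H1 lost,
#' RPA32 depleted; (b) lost, RPA32 present, hyperphosphorylated;
#' (c) RNase H1 bound, hyperphosphorylated; (other) bound, RPA32 present,
#' baseline phosphorylation. The phospho-RPA32 rate track is built from
#' Poisson RPA32 / pRPA32 tracks (baseline phospho multiplier
#' `prpa_baseline` < 1, hyperphosphorylated regions `prpa_hyper`) through
#' [log2_ratio()] with pseudocount 11.
#'
#' @param n Number of R-loops.
#' @param freqs Named fractions for categories `a`, `b`, `c` (remainder
#'   is `other`).
#' @param lambda0 Baseline Poisson rate (counts per 50 bp bin).
#' @param prpa_baseline,prpa_hyper Phospho multipliers.
#' @param seed Seed.
#' @return List with `rloops`, `rnh1_peaks`, `rnh1_lost`, `rpa32_peaks`,
#'   `prate` (`binned_track`), `assembly`, `truth` (planted categories).
#' @export
simulate_resolution_cohort <- function(n = 1000,
                                       freqs = c(a = 0.10, b = 0.05,
                                                 c = 0.40),
                                       lambda0 = 2, prpa_baseline = 0.5,
                                       prpa_hyper = 3, seed = 1) {
  stopifnot(sum(freqs) <= 1)
  .set_substream(seed, 4L)
  T_ <- 8000L
  counts <- floor(n * freqs)
  cat <- sample(c(rep("a_lost_rpa_depleted", counts[["a"]]),
                  rep("b_lost_hyperphos", counts[["b"]]),
                  rep("c_bound_hyperphos", counts[["c"]]),
                  rep("other", n - sum(counts))))
  base <- (seq_len(n) - 1L) * T_
  w <- round(stats::runif(n, 200, 2000))
  rl <- GRanges("chr1", IRanges(base + 3000L, base + 3000L + w - 1L))
  L <- n * T_ + T_
  si <- as_assembly(c(chr1 = L))

  pad <- function(idx) GRanges("chr1", IRanges(start(rl)[idx] - 100L,
                                               end(rl)[idx] + 100L))
  bound <- cat %in% c("c_bound_hyperphos", "other")
  lost <- cat %in% c("a_lost_rpa_depleted", "b_lost_hyperphos")
  rpa <- cat != "a_lost_rpa_depleted"
  hyper <- cat %in% c("b_lost_hyperphos", "c_bound_hyperphos")

  bin <- 50L
  nb <- ceiling(L / bin)
  lam_p <- rep(prpa_baseline * lambda0, nb)
  hyp_rl <- rl[hyper]
  for (i in seq_along(hyp_rl)) {
    b1 <- (start(hyp_rl)[i] - 1L) %/% bin + 1L
    b2 <- (end(hyp_rl)[i] - 1L) %/% bin + 1L
    lam_p[b1:b2] <- prpa_hyper * lambda0
  }
  rpa_track <- binned_track(list(chr1 = stats::rpois(nb, lambda0)),
                            bin, si, label = "RPA32")
  prpa_track <- binned_track(list(chr1 = stats::rpois(nb, lam_p)),
                             bin, si, label = "pRPA32")
  prate <- log2_ratio(prpa_track, rpa_track, pseudocount = 11)

  out_gr <- function(idx) {
    g <- if (any(idx)) pad(which(idx)) else GRanges()
    .set_assembly(g, si)
  }
  rl <- .set_assembly(rl, si)
  list(rloops = rl, rnh1_peaks = out_gr(bound), rnh1_lost = out_gr(lost),
       rpa32_peaks = out_gr(rpa), prate = prate, assembly = si,
       truth = data.frame(category = cat, stringsAsFactors = FALSE))
}

#' Synthetic track pair with planted differential regions
#'
#' Two Poisson count tracks on a 50 bp grid: condition 1 carries
#' `n_regions` planted regions of `region_bins` bins at `fold` times the
#' baseline rate; condition 2 is baseline everywhere.
#'
#' @param n_bins Total bins per track.
#' @param bin_size Bin width (bp).
#' @param n_regions,region_bins Planted region count and width (bins).
#' @param fold Planted rate multiplier.
#' @param lambda0 Baseline Poisson rate (counts/bin).
#' @param seed Seed.
#' @return List with `t1`, `t2` (`binned_track`s), `truth` (`GRanges` of
#'   planted regions), `assembly`.
#' @export
simulate_differential_pair <- function(n_bins = 4000, bin_size = 50,
                                       n_regions = 20, region_bins = 20,
                                       fold = 3, lambda0 = 10, seed = 1) {
  .set_substream(seed, 5L)
  L <- n_bins * bin_size
  si <- as_assembly(c(chr1 = L))
  spacing <- n_bins %/% n_regions
  stopifnot(spacing > region_bins + 10)
  start_bin <- (seq_len(n_regions) - 1L) * spacing + spacing %/% 4L
  lam1 <- rep(lambda0, n_bins)
  for (s in start_bin) lam1[s:(s + region_bins - 1L)] <- fold * lambda0
  t1 <- binned_track(list(chr1 = stats::rpois(n_bins, lam1)), bin_size, si,
                     label = "cond1")
  t2 <- binned_track(list(chr1 = stats::rpois(n_bins, lambda0)), bin_size,
                     si, label = "cond2")
  truth <- GRanges("chr1", IRanges((start_bin - 1L) * bin_size + 1L,
                                   (start_bin + region_bins - 1L) * bin_size))
  truth <- .set_assembly(truth, si)
  list(t1 = t1, t2 = t2, truth = truth, assembly = si)
}

#' Synthetic read-start tracks with planted fork-pausing bins
#'
#' Day-0 counts per 50 kb bin are Poisson(`mu`); a planted subset of bins
#' gets day-3 counts at `fold_true * mu` (Poisson), the rest stay at
#' `mu`. The day-3 library can be scaled by `lib_factor` (RPM
#' normalisation must cancel it). Bins are spread over 24 chromosomes so
#' genome-scale bin counts stay within integer coordinates.
#'
#' @param n_bins Total number of 50 kb bins (default 60000, a
#'   human-genome-scale count); ignored when `assembly` is given.
#' @param mu Baseline mean read starts per bin.
#' @param pausing_fraction Share of bins planted as pausing.
#' @param fold_true Planted rate ratio in pausing bins.
#' @param lib_factor Day-3 library scale factor.
#' @param bin_size Bin width (bp).
#' @param assembly Optional `Seqinfo`/named lengths to bin over; default
#'   is a synthetic 24-chromosome layout holding `n_bins` bins.
#' @param seed Seed.
#' @return List with `day3`, `day0` (`binned_track` counts), `truth`
#'   (`GRanges` of planted pausing bins), `assembly`.
#' @export
simulate_trael <- function(n_bins = 60000, mu = 50, pausing_fraction = 0.05,
                           fold_true = 2, lib_factor = 1,
                           bin_size = 50000, assembly = NULL, seed = 1) {
  .set_substream(seed, 6L)
  if (is.null(assembly)) {
    n_chr <- 24L
    per <- n_bins %/% n_chr
    sizes <- stats::setNames(rep(per * bin_size, n_chr),
                             paste0("chr", seq_len(n_chr)))
    si <- as_assembly(sizes)
  } else {
    si <- as_assembly(assembly)
  }
  nb_chr <- ceiling(seqlengths(si) / bin_size)
  n_bins <- sum(nb_chr)
  pausing <- sort(sample.int(n_bins, max(1L, round(n_bins *
                                                     pausing_fraction))))
  lam3 <- rep(mu, n_bins)
  lam3[pausing] <- fold_true * mu
  c0 <- stats::rpois(n_bins, mu)
  c3 <- stats::rpois(n_bins, lib_factor * lam3)
  grp <- rep(seq_along(nb_chr), nb_chr)
  split_bins <- function(v)
    stats::setNames(lapply(split(v, grp), as.numeric), seqnames(si))
  day0 <- binned_track(split_bins(c0), bin_size, si, label = "day0")
  day3 <- binned_track(split_bins(c3), bin_size, si, label = "day3")
  offs <- c(0L, cumsum(nb_chr))
  chr_i <- findInterval(pausing - 1L, offs, rightmost.closed = FALSE)
  bin_i <- (pausing - 1L) - offs[chr_i]
  truth <- GRanges(seqnames(si)[chr_i],
                   IRanges(bin_i * bin_size + 1L,
                           pmin((bin_i + 1L) * bin_size,
                                seqlengths(si)[chr_i])))
  truth <- .set_assembly(truth, si)
  list(day3 = day3, day0 = day0, truth = truth, assembly = si)
}

#' Simulate a fluorescence polarization titration
#'
#' Evaluates the ligand-depletion isotherm on the protein grid and adds
#' multiplicative Gaussian noise.
#'
#' @param K_D,L_T Molar parameters.
#' @param F_L,F_LP Free / saturated polarization.
#' @param noise_sd Multiplicative noise SD (0.01 = 1%).
#' @param grid Protein concentrations (molar); default 12 log-spaced
#'   points over 0.03--30 uM.
#' @param seed Seed.
#' @return List with `data` (data.frame `P_T`, `FP`) and `truth`
#'   (the parameters).
#' @export
simulate_fp <- function(K_D = 150e-9, L_T = 30e-9, F_L = 50, F_LP = 300,
                        noise_sd = 0.01,
                        grid = exp(seq(log(0.03e-6), log(30e-6),
                                       length.out = 12)),
                        seed = 1) {
  .set_substream(seed, 7L)
  F0 <- isotherm_value(grid, K_D, F_L, F_LP, L_T)
  FP <- F0 * (1 + stats::rnorm(length(grid), 0, noise_sd))
  list(data = data.frame(P_T = grid, FP = FP),
       truth = list(K_D = K_D, L_T = L_T, F_L = F_L, F_LP = F_LP,
                    noise_sd = noise_sd, seed = seed))
}

# Poisson track over the bundle assembly with multiplied rates inside
# the given region sets: regions is a list(list(gr=, mult=), ...).
.poisson_track <- function(assembly, bin, lambda0, regions, label) {
  si <- as_assembly(assembly)
  vals <- lapply(stats::setNames(seqnames(si), seqnames(si)), function(ch) {
    nb <- ceiling(seqlengths(si)[[ch]] / bin)
    lam <- rep(lambda0, nb)
    for (r in regions) {
      g <- r$gr[GenomeInfoDb::seqnames(r$gr) == ch]
      if (length(g) == 0) next
      b1 <- (start(g) - 1L) %/% bin + 1L
      b2 <- pmin((end(g) - 1L) %/% bin + 1L, nb)
      for (i in seq_along(g)) lam[b1[i]:b2[i]] <- r$mult * lambda0
    }
    stats::rpois(nb, lam)
  })
  binned_track(lapply(vals, as.numeric), bin, si, label = label)
}

# Place n peaks anchored near gene TSSs (offset into the gene body),
# avoiding overlap with intervals in `avoid` and with each other.
.gene_anchored_peaks <- function(genes, n, width_range, avoid = GRanges()) {
  g_ch <- as.character(GenomeInfoDb::seqnames(genes))
  g_st <- start(genes); g_en <- end(genes)
  g_plus <- as.character(strand(genes)) == "+"
  a_ch <- as.character(GenomeInfoDb::seqnames(avoid))
  a_st <- start(avoid); a_en <- end(avoid)
  chv <- character(n); stv <- integer(n); env <- integer(n)
  n_kept <- 0L
  tries <- 0L
  while (n_kept < n) {
    tries <- tries + 1L
    if (tries > 200L * n) stop("could not place ", n, " gene-anchored peaks")
    i <- sample.int(length(genes), 1)
    w <- round(stats::runif(1, width_range[1], width_range[2]))
    o <- round(stats::runif(1, 0, max(1, g_en[i] - g_st[i] - w)))
    st <- if (g_plus[i]) g_st[i] + o else g_en[i] - o - w + 1L
    en <- st + w - 1L
    ch <- g_ch[i]
    ai <- a_ch == ch
    if (any(ai) && any(st <= a_en[ai] & en >= a_st[ai])) next
    ki <- chv[seq_len(n_kept)] == ch
    if (any(ki) && any(st <= env[seq_len(n_kept)][ki] &
                       en >= stv[seq_len(n_kept)][ki])) next
    n_kept <- n_kept + 1L
    chv[n_kept] <- ch; stv[n_kept] <- st; env[n_kept] <- en
  }
  sort(GRanges(chv, IRanges(stv, env)), ignore.strand = TRUE)
}

#' Simulate the full multi-mark bundle on one genome
#'
#' Generates, on the configured genome: two conditions of R-loop peaks
#' (shared plus condition-specific), planted QPS motifs realising the
#' configured G-loop / template split for condition-1 R-loops, G4 peaks
#' over the motifs, TSS-anchored RNase H1 peaks for both conditions (with
#' a lost-in-condition-1 subset), RPA32 peaks, broad gamma-H2AX domains,
#' Poisson signal tracks for every mark (hyperphosphorylated pRPA32 in a
#' planted subset of R-loops), day0/day3 read-start tracks with planted
#' pausing bins, and an FP titration. Ground truth for every planted
#' quantity is returned alongside.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_bundle` (peaks, tracks, genome, truth).
#' @export
simulate_peaks_and_tracks <- function(config = sim_config()) {
  gg <- simulate_genome_and_genes(config)
  .set_substream(config$seed, 8L)
  si <- gg$assembly
  n <- config$n_rloops
  n_spec <- round(n * config$cond1_specific_fraction)
  n_shared <- n - n_spec

  shared <- .gene_anchored_peaks(gg$genes, n_shared,
                                 config$rloop_width_range)
  spec1 <- .gene_anchored_peaks(gg$genes, n_spec,
                                config$rloop_width_range, avoid = shared)
  spec2 <- .gene_anchored_peaks(gg$genes, n_spec,
                                config$rloop_width_range,
                                avoid = c(shared, spec1))
  rl1 <- sort(c(shared, spec1), ignore.strand = TRUE)
  rl2 <- sort(c(shared, spec2), ignore.strand = TRUE)

  # plant QPS for condition-1 R-loops per the configured split
  orient <- orient_rloops(rl1, gg$genes)
  assigned <- which(!is.na(mcols(orient)$txn_strand))
  n_g <- floor(length(assigned) * config$gloop_fraction)
  n_t <- floor(length(assigned) * config$template_fraction)
  lab <- sample(c(rep("gloop_like", n_g), rep("template_g4", n_t),
                  rep("no_g4", length(assigned) - n_g - n_t)))
  category <- rep("unassigned", length(rl1))
  category[assigned] <- lab
  txn <- mcols(orient)$txn_strand
  plant <- assigned[lab != "no_g4"]
  gap <- ifelse(lab[match(plant, assigned)] == "gloop_like",
                round(stats::runif(length(plant), 0,
                                   config$gloop_window - 1000)),
                round(stats::runif(length(plant), 200,
                                   config$gloop_window - 1000)))
  down <- (lab[match(plant, assigned)] == "gloop_like") ==
    (txn[plant] == "+")
  m_st <- ifelse(down, end(rl1)[plant] + gap + 1L,
                 start(rl1)[plant] - gap - 37L)
  m_st <- pmax(m_st, 128L)
  m_st <- pmin(m_st, seqlengths(si)[as.character(
    GenomeInfoDb::seqnames(rl1))[plant]] - 170L)
  qstr <- ifelse(lab[match(plant, assigned)] == "gloop_like", txn[plant],
                 ifelse(txn[plant] == "+", "-", "+"))
  sites <- GRanges(GenomeInfoDb::seqnames(rl1)[plant],
                   IRanges(m_st, width = 1L), strand = qstr)
  pl <- plant_qps(gg$genome, sites)
  genome <- pl$genome
  j1 <- sample.int(101L, length(pl$truth), replace = TRUE) - 1L
  j2 <- sample.int(101L, length(pl$truth), replace = TRUE) - 1L
  g4_peaks <- GRanges(GenomeInfoDb::seqnames(pl$truth),
                      IRanges(pmax(start(pl$truth) - j1, 1L),
                              end(pl$truth) + j2))
  g4_peaks <- GenomicRanges::trim(.set_assembly(g4_peaks, si))

  # resolution-failure planting: per-R-loop category with the configured
  # frequencies; RNase H1 binds R-loops of categories c/other in the
  # pre-RIS condition and additionally the a/b ("lost") R-loops in the
  # escaper condition; RPA32 flanks every R-loop except category a;
  # categories b/c are hyperphosphorylated
  rf <- config$resolution_freqs
  res_cat <- sample(c("a", "b", "c", "other"), length(rl1), replace = TRUE,
                    prob = c(rf[["a"]], rf[["b"]], rf[["c"]],
                             1 - sum(rf)))
  pad100 <- function(gr) GenomicRanges::trim(suppressWarnings(gr + 100L))
  # TSS-proximal narrow RNase H1 peaks plus R-loop-associated binding
  tss_peak <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::resize(tss_sites(gg$genes), 300L, fix = "center")))
  strand(tss_peak) <- "*"
  mcols(tss_peak) <- NULL
  rnh1_1 <- sort(c(tss_peak, pad100(rl1[res_cat %in% c("c", "other")])),
                 ignore.strand = TRUE)  # pre-RIS condition
  rnh1_lost <- sort(pad100(rl1[res_cat %in% c("a", "b")]),
                    ignore.strand = TRUE)
  rnh1_2 <- sort(c(rnh1_1, rnh1_lost), ignore.strand = TRUE)  # escaper
  hyper <- which(res_cat %in% c("b", "c"))
  rpa32 <- sort(pad100(rl1[res_cat != "a"]), ignore.strand = TRUE)

  gamma_h2ax <- .gene_anchored_peaks(gg$genes,
                                     max(3L, length(gg$genes) %/% 10L),
                                     c(5000, 20000))

  bin <- config$track_bin
  mk <- function(regions, label) .poisson_track(si, bin, config$lambda0,
                                                regions, label)
  e <- config$enrichment
  tracks <- list(
    drip1 = mk(list(list(gr = rl1, mult = e)), "DRIP_cond1"),
    drip2 = mk(list(list(gr = rl2, mult = e)), "DRIP_cond2"),
    gamma = mk(list(list(gr = gamma_h2ax, mult = 3)), "gH2AX"),
    rnh1_1 = mk(list(list(gr = rnh1_1, mult = e)), "RNaseH1_cond1"),
    rnh1_2 = mk(list(list(gr = rnh1_2, mult = e)), "RNaseH1_cond2"),
    rpa32 = mk(list(list(gr = rpa32, mult = e)), "RPA32"))
  # pRPA32: sub-stoichiometric baseline within RPA32 peaks, elevated in
  # the hyperphosphorylated R-loop subset (later region sets win)
  tracks$prpa32 <- .poisson_track(
    si, bin, config$lambda0,
    list(list(gr = rpa32, mult = e * config$prpa_baseline),
         list(gr = rl1[hyper], mult = e * config$prpa_hyper)),
    "pRPA32")
  n50 <- sum(ceiling(seqlengths(si) / 50000))
  trael <- simulate_trael(mu = 50,
                          pausing_fraction = min(0.5,
                                                 config$pausing_bins / n50),
                          assembly = si, seed = config$seed)
  fp <- simulate_fp(K_D = config$fp$K_D, L_T = config$fp$L_T,
                    F_L = config$fp$F_L, F_LP = config$fp$F_LP,
                    noise_sd = config$fp$noise_sd, grid = config$fp$grid,
                    seed = config$seed)
  structure(list(
    genome = genome, assembly = si, genes = gg$genes,
    rloops_cond1 = rl1, rloops_cond2 = rl2,
    rloops_cond1_specific = spec1,
    g4_peaks = g4_peaks, qps_truth = pl$truth,
    rnh1_cond1 = rnh1_1, rnh1_cond2 = rnh1_2, rnh1_lost = rnh1_lost,
    rpa32 = rpa32, gamma_h2ax = gamma_h2ax,
    tracks = tracks, trael = trael, fp = fp,
    truth = list(gloop_category = category,
                 resolution_category = res_cat,
                 hyperphos_idx = hyper,
                 pausing = trael$truth,
                 fp = fp$truth),
    config = config), class = "sim_bundle")
}

#' Write a simulated bundle to disk
#'
#' Emits genome.fa, genes.bed12, rloops_cond{1,2}.bed, g4.bed,
#' rnh1_{1,2}.bed, rnh1_lost.bed, rpa32.bed, gamma_h2ax.bed,
#' chrom.sizes, tracks/*.bedgraph, trael_day{0,3}.bedgraph, fp.csv and
#' truth.json. Regenerating with the same config reproduces identical
#' files.
#'
#' @param bundle A `sim_bundle` from [simulate_peaks_and_tracks()].
#' @param out_dir Output directory (created).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(file.path(out_dir, "tracks"), recursive = TRUE,
             showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_fasta(bundle$genome, p("genome.fa"))
  write_chrom_sizes(bundle$assembly, p("chrom.sizes"))
  exons <- mcols(bundle$genes)$exons
  names(exons) <- mcols(bundle$genes)$gene_id
  rtracklayer::export(exons, p("genes.bed12"), format = "BED")
  beds <- list(rloops_cond1 = bundle$rloops_cond1,
               rloops_cond2 = bundle$rloops_cond2,
               g4 = bundle$g4_peaks,
               rnh1_1 = bundle$rnh1_cond1, rnh1_2 = bundle$rnh1_cond2,
               rnh1_lost = bundle$rnh1_lost,
               rpa32 = bundle$rpa32, gamma_h2ax = bundle$gamma_h2ax)
  for (nm in names(beds)) write_intervals(beds[[nm]], p(paste0(nm, ".bed")))
  for (nm in names(bundle$tracks))
    write_bedgraph(bundle$tracks[[nm]],
                   p("tracks", paste0(nm, ".bedgraph")))
  write_bedgraph(bundle$trael$day0, p("trael_day0.bedgraph"))
  write_bedgraph(bundle$trael$day3, p("trael_day3.bedgraph"))
  utils::write.table(bundle$fp$data, p("fp.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  truth <- list(
    seed = bundle$config$seed,
    gloop_category = bundle$truth$gloop_category,
    resolution_category = bundle$truth$resolution_category,
    n_hyperphos = length(bundle$truth$hyperphos_idx),
    pausing_bins = data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(bundle$truth$pausing)),
      start0 = start(bundle$truth$pausing) - 1L,
      end = end(bundle$truth$pausing)),
    fp = bundle$truth$fp)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
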