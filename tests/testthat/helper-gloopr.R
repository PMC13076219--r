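suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# quick binned_track constructor on a single chromosome
one_chrom_track <- function(v, bin_size = 50, label = "") {
  binned_track(list(chr1 = as.numeric(v)), bin_size,
               c(chr1 = length(v) * bin_size), label = label)
}

# brute-force windowBed-style matching for the overlap oracle
brute_window_match <- function(a, b, window) {
  vapply(seq_along(a), function(i) {
    any(vapply(seq_along(b), function(j) {
      s1 <- start(a)[i]; e1 <- end(a)[i]
      s2 <- start(b)[j]; e2 <- end(b)[j]
      same <- as.character(seqnames(a))[i] == as.character(seqnames(b))[j]
      if (!same) return(FALSE)
      ov <- s1 <= e2 && s2 <= e1
      gap <- max(s1, s2) - min(e1, e2) - 1L
      ov || (gap >= 0 && gap < window)
    }, logical(1)))
  }, logical(1))
}

# per-region Jaccard of called regions against one truth interval
region_jaccard <- function(truth_i, calls) {
  h <- findOverlaps(truth_i, calls)
  if (length(h) == 0) return(0)
  hit <- reduce(calls[subjectHits(h)])
  inter <- sum(width(GenomicRanges::intersect(truth_i, hit)))
  uni <- sum(width(GenomicRanges::union(truth_i, hit)))
  inter / uni
}

random_dna_string <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
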