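#' Parameters for quadruplex-forming sequence (QPS) prediction
#'
#' Defaults follow the published scans: G4Hunter with word (window) size
#' 25 and threshold score 1.2; QGRS-style enumeration with maximum motif
#' length 30, minimum G-group size 2 and loop sizes 0-36 (loop lengths
#' are additionally bounded by the total-length constraint).
#'
#' @param window G4Hunter sliding-window size (bp).
#' @param threshold Minimum |mean window score| to call a hit.
#' @param max_run_cap Per-base score cap for long G/C runs (default 4).
#' @param qgrs_max_len Maximum QGRS motif length (bp).
#' @param qgrs_min_g Minimum G-group (tetrad-layer) size.
#' @param qgrs_loop_min,qgrs_loop_max Loop length bounds (bp).
#' @return A list of class `qps_params`.
#' @export
qps_params <- function(window = 25, threshold = 1.2, max_run_cap = 4,
                       qgrs_max_len = 30, qgrs_min_g = 2,
                       qgrs_loop_min = 0, qgrs_loop_max = 36) {
  stopifnot(window >= 1, threshold > 0, qgrs_min_g >= 2,
            qgrs_loop_min >= 0, qgrs_loop_min <= qgrs_loop_max)
  structure(list(window = as.integer(window), threshold = threshold,
                 max_run_cap = as.integer(max_run_cap),
                 qgrs_max_len = as.integer(qgrs_max_len),
                 qgrs_min_g = as.integer(qgrs_min_g),
                 qgrs_loop_min = as.integer(qgrs_loop_min),
                 qgrs_loop_max = as.integer(qgrs_loop_max)),
            class = "qps_params")
}

.as_seq_list <- function(x) {
  if (is(x, "DNAStringSet")) {
    s <- as.character(x)
    if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
    return(s)
  }
  if (is(x, "DNAString")) x <- as.character(x)
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(toupper(x))
  }
  stop("expected a DNA string, character vector or DNAStringSet")
}

#' G4Hunter per-base scores
#'
#' Each base in a maximal run of n guanines scores `+min(n, cap)`; each
#' base in a run of n cytosines scores `-min(n, cap)`; A, T and N score
#' 0 (N breaks runs). The mean of these scores over a window is the
#' G4Hunter propensity: positive for G4 potential on the given strand,
#' negative for the reverse complement.
#'
#' @param seq A single DNA string over A/C/G/T/N.
#' @param max_run_cap Run-length score cap (default 4).
#' @return Numeric vector, one score per base.
#' @export
g4hunter_base_scores <- function(seq, max_run_cap = 4) {
  x <- utf8ToInt(toupper(seq))
  ok <- x %in% c(65L, 67L, 71L, 84L, 78L)  # A C G T N
  if (!all(ok))
    stop("invalid character '", intToUtf8(x[which(!ok)[1]]),
         "' at position ", which(!ok)[1])
  r <- rle(x)
  cap <- pmin(r$lengths, max_run_cap)
  v <- numeric(length(r$values))
  v[r$values == 71L] <- cap[r$values == 71L]
  v[r$values == 67L] <- -cap[r$values == 67L]
  rep(v, r$lengths)
}

#' G4Hunter sliding-window mean scores
#'
#' Mean of the per-base scores over every window of length
#' `params$window`; value i covers bases `i .. i + window - 1`. This is
#' the quantity thresholded by [g4hunter_call()].
#'
#' @param seq A single DNA string.
#' @param params A [qps_params()] list.
#' @return Numeric vector of length `nchar(seq) - window + 1` (empty for
#'   shorter sequences).
#' @export
g4hunter_window_scores <- function(seq, params = qps_params()) {
  s <- g4hunter_base_scores(seq, params$max_run_cap)
  n <- length(s)
  w <- params$window
  if (n < w) return(numeric(0))
  cs <- c(0, cumsum(s))
  (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
}

# Trim a candidate span to begin and end on the scoring base (G for +,
# C for -); returns c(start, end) or NULL if none present.
.trim_to_base <- function(x, st, en, base) {
  idx <- which(x[st:en] == base)
  if (length(idx) == 0) return(NULL)
  c(st + idx[1] - 1L, st + idx[length(idx)] - 1L)
}

#' Call G4Hunter hits by sliding-window scoring
#'
#' Windows of length `params$window` whose mean base score satisfies
#' `|mean| >= params$threshold` are detected; overlapping or adjacent
#' same-sign windows are merged, the merged span is trimmed so it starts
#' and ends on a G (plus strand) or C (minus strand), and the mean score
#' is recomputed over the trimmed span. If merging drags the recomputed
#' mean below threshold, the hit falls back to the best single window in
#' the merged group. Strand is `+` for positive scores, `-` for negative.
#'
#' @param x DNA string(s): character vector (optionally named) or
#'   `DNAStringSet`; names become seqnames.
#' @param params A [qps_params()] list.
#' @return A `GRanges` with metadata `mean_score`, `method = "g4hunter"`.
#' @export
g4hunter_call <- function(x, params = qps_params()) {
  seqs <- .as_seq_list(x)
  w <- params$window
  thr <- params$threshold
  rows <- list()
  for (ch in names(seqs)) {
    s <- g4hunter_base_scores(seqs[[ch]], params$max_run_cap)
    n <- length(s)
    if (n < w) next
    xint <- utf8ToInt(toupper(seqs[[ch]]))
    cs <- c(0, cumsum(s))
    wmean <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
    for (sgn in c(1, -1)) {
      idx <- which(sgn * wmean >= thr)
      if (length(idx) == 0) next
      brk <- which(diff(idx) > w)  # windows further apart neither
                                   # overlap nor touch
      gs <- c(1L, brk + 1L)
      ge <- c(brk, length(idx))
      base <- if (sgn > 0) 71L else 67L
      for (k in seq_along(gs)) {
        grp <- idx[gs[k]:ge[k]]
        span <- c(min(grp), max(grp) + w - 1L)
        tr <- .trim_to_base(xint, span[1], span[2], base)
        m <- if (is.null(tr)) 0 else mean(s[tr[1]:tr[2]])
        if (is.null(tr) || sgn * m < thr) {
          # fall back to the strongest single window of the group
          i <- grp[which.max(sgn * wmean[grp])]
          tr <- .trim_to_base(xint, i, i + w - 1L, base)
          if (is.null(tr)) next
          m <- mean(s[tr[1]:tr[2]])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = tr[1], end = tr[2], mean_score = m,
          strand = if (sgn > 0) "+" else "-")
      }
    }
  }
  if (length(rows) == 0)
    return(GRanges(mean_score = numeric(), method = character()))
  df <- do.call(rbind, rows)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                mean_score = df$mean_score, method = "g4hunter")
  sort(gr, ignore.strand = TRUE)
}

#' QGRS-style quadruplex motif enumeration
#'
#' Enumerates substrings of the form `G{g} L1 G{g} L2 G{g} L3 G{g}` with
#' `g >= qgrs_min_g`, loop lengths within the configured bounds and total
#' length `<= qgrs_max_len`, on both strands (minus strand scanned on the
#' reverse complement, coordinates mapped back). Overlapping candidates
#' on the same strand are resolved greedily: larger g first, then shorter
#' total length, then leftmost start.
#'
#' @param x DNA string(s) or `DNAStringSet`.
#' @param params A [qps_params()] list.
#' @return A `GRanges` with metadata `n_tetrad_layers` (g), `loop1..3`,
#'   `method = "qgrs"`.
#' @export
qgrs_scan <- function(x, params = qps_params()) {
  seqs <- .as_seq_list(x)
  out <- list()
  for (ch in names(seqs)) {
    sq <- seqs[[ch]]
    n <- nchar(sq)
    for (str in c("+", "-")) {
      s <- if (str == "+") sq else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
      cand <- .qgrs_candidates_cpp(s, params$qgrs_min_g,
                                   params$qgrs_loop_min,
                                   params$qgrs_loop_max,
                                   params$qgrs_max_len)
      if (nrow(cand) == 0) next
      start1 <- if (str == "+") cand[, "start0"] + 1L
                else n - (cand[, "start0"] + cand[, "len"]) + 1L
      end1 <- start1 + cand[, "len"] - 1L
      # loops are reported 5'->3' on the hit's own strand
      ord <- order(-cand[, "g"], cand[, "len"], start1)
      kept <- integer(0)
      ks <- integer(0); ke <- integer(0)
      for (i in ord) {
        if (any(start1[i] <= ke & end1[i] >= ks)) next
        kept <- c(kept, i)
        ks <- c(ks, start1[i]); ke <- c(ke, end1[i])
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = start1[kept], end = end1[kept], strand = str,
        g = cand[kept, "g"], loop1 = cand[kept, "loop1"],
        loop2 = cand[kept, "loop2"], loop3 = cand[kept, "loop3"])
    }
  }
  if (length(out) == 0)
    return(GRanges(n_tetrad_layers = integer(), loop1 = integer(),
                   loop2 = integer(), loop3 = integer(),
                   method = character()))
  df <- do.call(rbind, out)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                n_tetrad_layers = df$g, loop1 = df$loop1, loop2 = df$loop2,
                loop3 = df$loop3, method = "qgrs")
  sort(gr, ignore.strand = TRUE)
}

#' Scan QPS hits with one or both methods
#'
#' @param x DNA string(s) or `DNAStringSet`.
#' @param params A [qps_params()] list.
#' @param method `"g4hunter"`, `"qgrs"` or `"both"`.
#' @return A `GRanges` of QPS hits.
#' @export
scan_qps <- function(x, params = qps_params(),
                     method = c("g4hunter", "qgrs", "both")) {
  method <- match.arg(method)
  if (method == "g4hunter") return(g4hunter_call(x, params))
  if (method == "qgrs") return(qgrs_scan(x, params))
  g <- g4hunter_call(x, params)
  q <- qgrs_scan(x, params)
  mcols(g) <- S4Vectors::DataFrame(method = mcols(g)$method,
                                   score = mcols(g)$mean_score)
  mcols(q) <- S4Vectors::DataFrame(method = mcols(q)$method,
                                   score = as.numeric(mcols(q)$n_tetrad_layers))
  sort(c(g, q), ignore.strand = TRUE)
}

#' Write QPS hits as BED6 (+ score TSV)
#'
#' BED score is `1000 * min(|mean_score| / 2, 1)` for browser display;
#' the exact scores live in a companion `.scores.tsv`.
#'
#' @param hits `GRanges` from [g4hunter_call()] / [qgrs_scan()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_qps_bed <- function(hits, path) {
  sc <- if (!is.null(mcols(hits)$mean_score)) abs(mcols(hits)$mean_score)
        else as.numeric(mcols(hits)$n_tetrad_layers)
  out <- hits
  mcols(out) <- S4Vectors::DataFrame(
    name = mcols(hits)$method,
    score = round(1000 * pmin(sc / 2, 1)))
  rtracklayer::export(out, path, format = "BED")
  utils::write.table(
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(hits)),
               start0 = start(hits) - 1L, end = end(hits),
               strand = as.character(strand(hits)), score = sc),
    paste0(path, ".scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
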