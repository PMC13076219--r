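#' Reference-point signal matrix and metaplot
#'
#' Builds the regions x columns matrix of mean track signal around anchor
#' midpoints (computeMatrix reference-point style) and its column-wise
#' mean (the metaplot). In `strand_oriented` mode the columns of anchors
#' on the minus strand are reversed, so column order runs in
#' transcription direction.
#'
#' @param track A `binned_track`.
#' @param anchors `GRanges`; the reference point is the interval midpoint.
#' @param flank Half-window (bp); columns cover \[-flank, +flank).
#' @param col_bin Column width (bp); `flank` must be a multiple.
#' @param mode `"center"` or `"strand_oriented"`.
#' @return An object of class `signal_matrix`: list with `matrix`
#'   (anchors x columns), `metaplot` (column means), `offsets` (bp of
#'   column left edges relative to the anchor point), `oob` (logical
#'   matrix flagging columns extending beyond the chromosome).
#' @export
signal_matrix <- function(track, anchors, flank, col_bin,
                          mode = c("center", "strand_oriented")) {
  mode <- match.arg(mode)
  if (flank %% col_bin != 0) stop("flank must be a multiple of col_bin")
  C <- as.integer(2 * flank / col_bin)
  n <- length(anchors)
  chrom <- as.character(GenomeInfoDb::seqnames(anchors))
  mid0 <- (start(anchors) - 1L + end(anchors)) %/% 2L
  off <- seq.int(-flank, flank - col_bin, by = col_bin)
  s0 <- rep(mid0, each = C) + rep(off, times = n)
  e0 <- s0 + col_bin
  m <- matrix(.track_span_means(track, rep(chrom, each = C), s0, e0),
              nrow = n, ncol = C, byrow = TRUE)
  L <- seqlengths(track$seqinfo)[chrom]
  oob <- matrix(rep(s0 < 0, 1) | e0 > rep(L, each = C),
                nrow = n, ncol = C, byrow = TRUE)
  if (mode == "strand_oriented" && n > 0) {
    neg <- as.character(strand(anchors)) == "-"
    m[neg, ] <- m[neg, C:1, drop = FALSE]
    oob[neg, ] <- oob[neg, C:1, drop = FALSE]
  }
  structure(list(matrix = m,
                 metaplot = if (n > 0) colMeans(m) else rep(NA_real_, C),
                 offsets = off, flank = flank, col_bin = col_bin,
                 mode = mode, oob = oob),
            class = "signal_matrix")
}

#' Write a signal matrix as TSV
#' @param sm A `signal_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(sm, path) {
  m <- sm$matrix
  colnames(m) <- sm$offsets
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Fingerprint (Lorenz) curve of a track
#'
#' Bins are sorted ascending by value; the curve plots cumulative signal
#' fraction against cumulative bin fraction. A perfectly uniform track
#' follows the diagonal (AUC 0.5); focal signal pushes the curve down
#' (AUC toward 0). Quantifies e.g. how uniformly a damage mark is spread
#' over the genome.
#'
#' @param track A `binned_track` with positive total signal.
#' @return List with `x`, `y` (monotone, in \[0,1\], including the
#'   origin) and `auc` (trapezoid area, in \[0, 0.5\]).
#' @export
fingerprint <- function(track) {
  v <- unlist(track$values, use.names = FALSE)
  v <- v[!is.na(v)]
  tot <- sum(v)
  if (length(v) == 0 || tot <= 0) stop("track has no positive signal")
  v <- sort(v)
  y <- c(0, cumsum(v) / tot)
  x <- c(0, seq_along(v) / length(v))
  auc <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  list(x = x, y = y, auc = auc)
}

#' Rebin a track to a coarser grid by averaging
#'
#' @param track A `binned_track`.
#' @param bin_size New bin width; must be a multiple of the current one.
#' @return A `binned_track` on the coarser grid (bin value = mean of the
#'   constituent fine bins, matching multiBigwigSummary averaging).
#' @export
rebin_track <- function(track, bin_size) {
  if (bin_size == track$bin_size) return(track)
  if (bin_size %% track$bin_size != 0)
    stop("new bin_size must be a multiple of ", track$bin_size)
  k <- bin_size %/% track$bin_size
  vals <- lapply(track$values, function(v) {
    n_out <- ceiling(length(v) / k)
    pad <- rep(NA_real_, n_out * k - length(v))
    m <- matrix(c(v, pad), nrow = k)
    colMeans(m, na.rm = TRUE)
  })
  binned_track(vals, bin_size, track$seqinfo,
               total_units = track$total_units, label = track$label)
}

#' Multi-sample summary: Spearman correlation and PCA
#'
#' Tracks are rebinned to `bin_size` by averaging; Spearman correlations
#' are computed over all shared bins, and PCA over the `ntop`
#' highest-variance bins (samples projected onto the principal axes of
#' the centered sample-by-bin matrix; component signs are arbitrary).
#'
#' @param tracks List of >= 2 `binned_track`s on a common assembly.
#' @param bin_size Summary bin width (bp, default 10000).
#' @param ntop Number of top-variance bins used for PCA (default 1000).
#' @return List with `matrix` (bins x samples), `spearman`
#'   (samples x samples), `pca_coords` (samples x components), `sdev`,
#'   `bin_size`, `ntop`.
#' @export
sample_summary <- function(tracks, bin_size = 10000, ntop = 1000) {
  if (length(tracks) < 2) stop("need at least 2 tracks")
  for (i in 2:length(tracks)) .track_check_pair(tracks[[1]], tracks[[i]])
  reb <- lapply(tracks, rebin_track, bin_size = bin_size)
  m <- vapply(reb, function(t) unlist(t$values, use.names = FALSE),
              numeric(length(unlist(reb[[1]]$values))))
  labels <- vapply(seq_along(tracks), function(i) {
    l <- tracks[[i]]$label
    if (nzchar(l)) l else paste0("sample", i)
  }, character(1))
  colnames(m) <- labels
  sp <- stats::cor(m, method = "spearman")
  vars <- apply(m, 1, stats::var)
  top <- order(vars, decreasing = TRUE)[seq_len(min(ntop, nrow(m)))]
  pca <- stats::prcomp(t(m[top, , drop = FALSE]), center = TRUE,
                       scale. = FALSE)
  list(matrix = m, spearman = sp, pca_coords = pca$x, sdev = pca$sdev,
       bin_size = bin_size, ntop = ntop)
}
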