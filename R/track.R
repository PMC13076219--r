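#' Binned signal tracks
#'
#' A `binned_track` is fixed-bin-size numeric signal per chromosome,
#' carrying the library size used for normalisation. It is the carrier of
#' coverage, log2 ratio ("rate") and likelihood-ratio signal throughout
#' the package; bedGraph is the interchange format on disk.
#'
#' @param values Named list of numeric vectors, one per chromosome, of
#'   length `ceiling(chrom_length / bin_size)`.
#' @param bin_size Bin width (bp).
#' @param assembly `Seqinfo` or named chromosome lengths.
#' @param total_units Library size used for normalisation (reads or total
#'   signal); `NA` when not applicable.
#' @param label Sample tag.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(values, bin_size, assembly,
                         total_units = NA_real_, label = "") {
  si <- as_assembly(assembly)
  stopifnot(bin_size >= 1, is.list(values), !is.null(names(values)))
  sl <- seqlengths(si)
  if (!setequal(names(values), seqnames(si)))
    stop("track chromosomes do not match assembly")
  values <- values[seqnames(si)]
  nb <- ceiling(sl / bin_size)
  ok <- vapply(seqnames(si), function(ch) length(values[[ch]]) == nb[[ch]],
               logical(1))
  if (!all(ok))
    stop("bin vector length mismatch for: ",
         paste(seqnames(si)[!ok], collapse = ", "))
  structure(list(values = values, bin_size = as.integer(bin_size),
                 seqinfo = si, total_units = total_units, label = label),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat("binned_track '", x$label, "': ", length(x$values),
      " chromosome(s), bin ", x$bin_size, " bp, total_units = ",
      format(x$total_units), "\n", sep = "")
  invisible(x)
}

.track_check_pair <- function(a, b) {
  stopifnot(inherits(a, "binned_track"), inherits(b, "binned_track"))
  if (a$bin_size != b$bin_size)
    stop("bin sizes differ (", a$bin_size, " vs ", b$bin_size, ")")
  if (!identical(seqlengths(a$seqinfo), seqlengths(b$seqinfo)))
    stop("track assemblies differ")
  invisible(TRUE)
}

# Per-chromosome binning of a per-base RleList: sum over each bin.
.bin_sums <- function(cov, bin_size) {
  lapply(stats::setNames(names(cov), names(cov)), function(ch) {
    r <- cov[[ch]]
    L <- length(r)
    starts <- seq.int(1L, L, by = bin_size)
    v <- IRanges::Views(r, start = starts,
                        end = pmin(starts + bin_size - 1L, L))
    as.numeric(IRanges::viewSums(v))
  })
}

#' Read a bedGraph file onto a fixed bin grid
#'
#' Records must be sorted and non-overlapping within each chromosome.
#' Values are resampled by coverage-weighted mean (uncovered bases count
#' as 0), which conserves total signal when record boundaries align with
#' bins.
#'
#' @param path bedGraph path (4 columns).
#' @param bin_size Target bin width (bp).
#' @param assembly `Seqinfo` or named lengths; inferred from the records
#'   (max end per chromosome) when omitted.
#' @param label Sample tag.
#' @return A `binned_track`.
#' @export
read_bedgraph <- function(path, bin_size, assembly = NULL, label = "") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (is.null(assembly)) {
    if (length(gr) == 0) stop("empty bedGraph and no assembly given")
    ends <- tapply(end(gr), as.character(GenomeInfoDb::seqnames(gr)), max)
    assembly <- stats::setNames(as.integer(ends), names(ends))
  }
  si <- as_assembly(assembly)
  for (ch in unique(as.character(GenomeInfoDb::seqnames(gr)))) {
    g <- gr[GenomeInfoDb::seqnames(gr) == ch]
    if (is.unsorted(start(g)))
      stop("'", path, "': records not sorted on ", ch, " (record ",
           which(diff(start(g)) < 0)[1] + 1L, ")")
    if (length(g) > 1 && any(start(g)[-1] <= end(g)[-length(g)]))
      stop("'", path, "': overlapping records on ", ch, " (record ",
           which(start(g)[-1] <= end(g)[-length(g)])[1] + 1L, ")")
  }
  if (length(gr)) .check_within_assembly(gr, si)
  GenomeInfoDb::seqlevels(gr) <- seqnames(si)
  seqinfo(gr) <- si
  cov <- GenomicRanges::coverage(gr, weight = if (length(gr)) gr$score else 1)
  vals <- lapply(.bin_sums(cov, bin_size), function(v) v / bin_size)
  binned_track(vals, bin_size, si,
               total_units = sum(vapply(cov, function(r)
                 sum(as.numeric(runValue(r)) * runLength(r)), numeric(1))),
               label = label)
}

#' Write a binned track as bedGraph
#'
#' Runs of equal-valued bins are collapsed; zero bins are omitted, except
#' for NA bins which are always omitted.
#'
#' @param track A `binned_track`.
#' @param path Output path.
#' @param keep_zero Emit zero-valued runs too (needed for exact
#'   round-trips of tracks containing genuine zeros). Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, keep_zero = FALSE) {
  bs <- track$bin_size
  grl <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- !is.na(r$values) & (keep_zero | r$values != 0)
    if (!any(keep)) return(GRanges())
    L <- seqlengths(track$seqinfo)[[ch]]
    GRanges(ch, IRanges((starts[keep] - 1L) * bs + 1L,
                        pmin(ends[keep] * bs, L)),
            score = r$values[keep])
  })
  gr <- suppressWarnings(do.call(c, grl))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Binned coverage of intervals or read-start positions
#'
#' Interval inputs are counted by fractional bin occupancy (an interval
#' covering half a bin contributes 0.5); width-1 position inputs (read
#' 5' starts) are counted integrally, one count per position. Raw values
#' can be normalised to RPM (`value * 1e6 / total_units`) or RPKM
#' (`value * 1e9 / (total_units * bin_size)`).
#'
#' @param x `GRanges` of intervals or width-1 positions.
#' @param assembly `Seqinfo` or named chromosome lengths.
#' @param bin_size Bin width (bp); default 50.
#' @param normalization `"raw"`, `"RPKM"` or `"RPM"`.
#' @param total_units Library size; defaults to `length(x)`.
#' @param counting `"auto"` (positions iff all widths are 1),
#'   `"fractional"`, or `"positions"`.
#' @param label Sample tag.
#' @return A `binned_track`.
#' @export
bin_coverage <- function(x, assembly, bin_size = 50,
                         normalization = c("raw", "RPKM", "RPM"),
                         total_units = NULL,
                         counting = c("auto", "fractional", "positions"),
                         label = "") {
  normalization <- match.arg(normalization)
  counting <- match.arg(counting)
  si <- as_assembly(assembly)
  if (length(x)) .check_within_assembly(x, si)
  if (counting == "auto")
    counting <- if (length(x) && all(width(x) == 1L)) "positions"
                else "fractional"
  if (is.null(total_units)) total_units <- length(x)
  if (normalization != "raw" && total_units == 0)
    stop("total_units is 0; cannot ", normalization, "-normalise")
  x2 <- x
  GenomeInfoDb::seqlevels(x2) <- seqnames(si)
  seqinfo(x2) <- si
  cov <- GenomicRanges::coverage(x2)
  vals <- .bin_sums(cov, bin_size)
  if (counting == "fractional")
    vals <- lapply(vals, function(v) v / bin_size)
  scale <- switch(normalization,
                  raw = 1,
                  RPM = 1e6 / total_units,
                  RPKM = 1e9 / (total_units * bin_size))
  vals <- lapply(vals, function(v) v * scale)
  binned_track(vals, bin_size, si, total_units = total_units, label = label)
}

#' Per-bin log2 ratio of two tracks
#'
#' Computes `log2((a + pseudocount) / (b + pseudocount))` bin-wise -- the
#' "rate" track construction (e.g. phospho-RPA32 over RPA32 with
#' pseudocount 11 on 50 bp bins).
#'
#' @param a,b `binned_track`s on the same grid.
#' @param pseudocount Added to both tracks (default 11).
#' @return A `binned_track` of log2 ratios.
#' @export
log2_ratio <- function(a, b, pseudocount = 11) {
  .track_check_pair(a, b)
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 &&
      any(vapply(b$values, function(v) any(v == 0), logical(1))))
    stop("zero bins in denominator; use a positive pseudocount")
  vals <- Map(function(x, y) log2((x + pseudocount) / (y + pseudocount)),
              a$values, b$values)
  binned_track(vals, a$bin_size, a$seqinfo, total_units = NA_real_,
               label = paste0("log2(", a$label, "/", b$label, ")"))
}

# Mean track value over 0-based half-open genomic spans [s0, e0), treating
# everything outside the chromosome as 0. Uses prefix integrals, O(1)/span.
.track_span_means <- function(track, chrom, s0, e0) {
  out <- numeric(length(s0))
  bs <- track$bin_size
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    v <- track$values[[ch]]
    if (is.null(v)) stop("chromosome ", ch, " absent from track")
    L <- seqlengths(track$seqinfo)[[ch]]
    cs <- c(0, cumsum(v)) * bs
    integral <- function(p) {
      p <- pmin(pmax(p, 0), L)
      k <- p %/% bs
      r <- p - k * bs
      cs[k + 1L] + r * v[pmin(k + 1L, length(v))]
    }
    out[i] <- (integral(e0[i]) - integral(s0[i])) / (e0[i] - s0[i])
  }
  out
}

#' Mean track signal over intervals
#'
#' @param track A `binned_track`.
#' @param regions `GRanges`.
#' @param flank Extension on both sides (bp).
#' @return Numeric vector, one mean per region.
#' @export
track_region_mean <- function(track, regions, flank = 0) {
  .track_span_means(track,
                    as.character(GenomeInfoDb::seqnames(regions)),
                    start(regions) - 1L - flank,
                    end(regions) + flank)
}
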