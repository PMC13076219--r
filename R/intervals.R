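#' Read peak / gene interval files (BED dialects)
#'
#' Reads BED3/BED6/BED12 and ENCODE narrowPeak into a sorted `GRanges`.
#' BED coordinates on disk are 0-based half-open; the returned `GRanges`
#' uses the usual Bioconductor 1-based closed convention, and
#' [write_intervals()] restores BED semantics on export. BED12 input
#' yields gene models: `gene_id` from the name column and an `exons`
#' metadata column (a `GRangesList` built from blockStarts/blockSizes).
#'
#' @param path Path to a tab-separated interval file.
#' @param dialect One of `"bed3"`, `"bed6"`, `"narrowPeak"`, `"bed12"`.
#' @param assembly Optional assembly (`Seqinfo` or named lengths); when
#'   given, intervals are bound-checked and the seqinfo attached.
#' @return A sorted `GRanges`; for `"bed12"`, with `gene_id` and `exons`
#'   metadata columns.
#' @export
read_intervals <- function(path,
                           dialect = c("bed6", "bed3", "narrowPeak", "bed12"),
                           assembly = NULL) {
  dialect <- match.arg(dialect)
  ncols <- c(bed3 = 3L, bed6 = 6L, narrowPeak = 10L, bed12 = 12L)[dialect]
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           comment.char = "#", quote = "")
  if (ncol(raw) < ncols)
    stop("'", path, "': ", dialect, " requires >= ", ncols,
         " columns, found ", ncol(raw))
  start0 <- suppressWarnings(as.numeric(raw[[2]]))
  end0 <- suppressWarnings(as.numeric(raw[[3]]))
  bad <- is.na(start0) | is.na(end0) | start0 < 0 | start0 >= end0
  if (any(bad))
    stop("'", path, "' row ", which(bad)[1],
         ": invalid interval [", raw[[2]][which(bad)[1]], ", ",
         raw[[3]][which(bad)[1]], ") (need 0 <= start < end)")
  if (ncols >= 6) {
    strand <- raw[[6]]
    if (!all(strand %in% c("+", "-", ".")))
      stop("'", path, "' row ", which(!strand %in% c("+", "-", "."))[1],
           ": invalid strand character")
  }
  gr <- rtracklayer::import(
    path, format = "BED",
    extraCols = if (dialect == "narrowPeak")
      c(signalValue = "numeric", pValue = "numeric",
        qValue = "numeric", peak = "integer") else character())
  if (dialect == "bed3") mcols(gr) <- NULL
  if (dialect == "bed12") {
    blk <- mcols(gr)$blocks  # exon ranges relative to each interval start
    exons <- GenomicRanges::GRangesList(lapply(seq_along(gr), function(i) {
      GRanges(GenomeInfoDb::seqnames(gr)[i],
              IRanges::shift(blk[[i]], start(gr)[i] - 1L),
              strand = strand(gr)[i])
    }))
    mcols(gr) <- S4Vectors::DataFrame(
      gene_id = if (!is.null(mcols(gr)$name)) mcols(gr)$name
                else paste0("gene", seq_along(gr)),
      exons = exons)
  }
  if (!is.null(assembly)) {
    si <- as_assembly(assembly)
    .check_within_assembly(gr, si)
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(si)
    seqinfo(gr) <- si
  }
  sort(gr, ignore.strand = TRUE)
}

#' Write intervals as BED
#'
#' @param gr A `GRanges` (name/score/strand metadata used when present).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Merge overlapping and book-ended intervals
#'
#' Strand-blind union of the input bases; book-ended intervals (0 bp gap)
#' are merged, matching `bedtools merge` defaults.
#'
#' @param peaks A `GRanges`.
#' @return A disjoint `GRanges` covering the same bases.
#' @export
merge_intervals <- function(peaks) {
  GenomicRanges::reduce(peaks, ignore.strand = TRUE, min.gapwidth = 1L)
}

# Map the windowBed convention (match iff >=1 nt overlap, or edge gap
# strictly less than `window`) onto findOverlaps maxgap.
.window_maxgap <- function(window) {
  stopifnot(window >= 0)
  if (window == 0) -1L else as.integer(window) - 1L
}

.check_same_assembly <- function(a, b) {
  sla <- seqlengths(a); slb <- seqlengths(b)
  shared <- intersect(names(sla)[!is.na(sla)], names(slb)[!is.na(slb)])
  if (length(shared) && any(sla[shared] != slb[shared]))
    stop("assemblies disagree on chromosome length(s): ",
         paste(shared[sla[shared] != slb[shared]], collapse = ", "))
  invisible(TRUE)
}

#' Window-tolerant interval overlap (windowBed semantics)
#'
#' An interval of `a` matches an interval of `b` iff they share at least
#' one nucleotide, or the gap between their nearest edges is strictly
#' less than `window`. `window = 0` reduces to plain >=1 nt overlap
#' (book-ended intervals do not match). Strand is ignored.
#'
#' @param a,b `GRanges`.
#' @param window Distance tolerance (bp, >= 0).
#' @return A list with `match` (logical, one per interval of `a`) and
#'   `pairs` (two-column matrix of matching a/b indices).
#' @export
window_overlap <- function(a, b, window = 0) {
  .check_same_assembly(a, b)
  # disjoint seqlevel sets are a legitimate no-match case, not a warning
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(a, b, maxgap = .window_maxgap(window),
                                ignore.strand = TRUE))
  match <- logical(length(a))
  match[queryHits(hits)] <- TRUE
  list(match = match,
       pairs = cbind(a = queryHits(hits), b = subjectHits(hits)))
}

#' Percentage of the genome covered by a peak set
#'
#' @param peaks `GRanges` (merged internally; strand ignored).
#' @param assembly `Seqinfo` or named chromosome lengths.
#' @return Percentage in \[0, 100\].
#' @export
genome_coverage_percent <- function(peaks, assembly) {
  si <- as_assembly(assembly)
  if (length(peaks) == 0) return(0)
  .check_within_assembly(peaks, si)
  100 * sum(as.numeric(width(merge_intervals(peaks)))) /
    sum(as.numeric(seqlengths(si)))
}

#' Transcription start / end sites of gene models
#'
#' @param genes Stranded `GRanges` of gene bodies.
#' @return Width-1 `GRanges` at the TSS (resp. TES).
#' @export
tss_sites <- function(genes) GenomicRanges::resize(genes, 1L, fix = "start")

#' @rdname tss_sites
#' @export
tes_sites <- function(genes) GenomicRanges::resize(genes, 1L, fix = "end")

#' Assign each peak to one genomic feature category
#'
#' Each peak is classified by the position of its midpoint, using the
#' priority order promoter > TSS > TES > exon > intron > intergenic.
#' Defaults: promoter = \[TSS - 2000, TSS + 500) in transcription
#' coordinates; TSS / TES regions extend `tss_flank` / `tes_flank` bp on
#' both sides of the site. Genes carrying an `exons` metadata column
#' (e.g. from BED12) distinguish exon from intron; for genes without
#' exon structure the whole body counts as exonic.
#'
#' @param peaks `GRanges` of peaks.
#' @param genes Stranded `GRanges` of gene models.
#' @param promoter_upstream,promoter_downstream Promoter extent around the
#'   TSS (bp upstream / downstream in transcription direction).
#' @param tss_flank,tes_flank Half-widths of the TSS / TES categories (bp).
#' @return A list with `category` (factor, one level per peak) and
#'   `distribution` (named counts summing to `length(peaks)`).
#' @export
annotate_features <- function(peaks, genes,
                              promoter_upstream = 2000,
                              promoter_downstream = 500,
                              tss_flank = 500, tes_flank = 500) {
  levels <- c("promoter", "TSS", "TES", "exon", "intron", "intergenic")
  if (length(peaks) == 0) {
    cat0 <- factor(character(), levels = levels)
    return(list(category = cat0, distribution = table(cat0)))
  }
  # midpoint of [s, e] in 0-based half-open coordinates, as a width-1 range
  mid0 <- (start(peaks) - 1L + end(peaks)) %/% 2L
  mids <- GRanges(GenomeInfoDb::seqnames(peaks),
                  IRanges(mid0 + 1L, width = 1L))
  hit_any <- function(region) {
    if (length(region) == 0) return(logical(length(mids)))
    IRanges::overlapsAny(mids, region, ignore.strand = TRUE)
  }
  prom <- suppressWarnings(GenomicRanges::promoters(
    genes, upstream = promoter_upstream, downstream = promoter_downstream))
  prom <- GenomicRanges::trim(prom)
  tssr <- suppressWarnings(tss_sites(genes) + tss_flank)
  tesr <- suppressWarnings(tes_sites(genes) + tes_flank)
  ex <- if (!is.null(mcols(genes)$exons)) unlist(mcols(genes)$exons)
        else genes
  cat <- rep("intergenic", length(mids))
  cat[hit_any(genes)] <- "intron"
  cat[hit_any(ex)] <- "exon"
  cat[hit_any(GenomicRanges::trim(tesr))] <- "TES"
  cat[hit_any(GenomicRanges::trim(tssr))] <- "TSS"
  cat[hit_any(prom)] <- "promoter"
  cat <- factor(cat, levels = levels)
  list(category = cat, distribution = table(cat))
}
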