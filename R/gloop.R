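#' Orient R-loops by transcription direction
#'
#' Each R-loop peak is assigned to the gene with the largest base overlap;
#' R-loops overlapping no gene fall back to the nearest gene within
#' `max_dist` bp (edge gap), and are otherwise unassigned. Ties are broken
#' deterministically: larger overlap, then longer gene, then lexicographic
#' `gene_id`. The transcribed (sense) strand of the assigned gene becomes
#' the R-loop's `txn_strand`; the template strand is its opposite -- the
#' displaced single strand of the R-loop has the sequence of the
#' non-template strand.
#'
#' @param rloops `GRanges` of R-loop peaks.
#' @param genes Stranded `GRanges` with a `gene_id` metadata column.
#' @param max_dist Maximum edge gap for nearest-gene fallback (bp).
#' @return `rloops` with metadata columns `gene_id`, `txn_strand`,
#'   `template_strand` (all `NA` when unassigned) and `assignment`
#'   (`"overlap"`, `"nearest"`, `"unassigned"`).
#' @export
orient_rloops <- function(rloops, genes, max_dist = 3000) {
  if (is.null(mcols(genes)$gene_id)) stop("genes need a gene_id column")
  if (any(!as.character(strand(genes)) %in% c("+", "-")))
    stop("genes must be stranded (+/-)")
  n <- length(rloops)
  gene_id <- rep(NA_character_, n)
  txn <- rep(NA_character_, n)
  assignment <- rep("unassigned", n)

  pick <- function(q, s, key1) {
    # per query q, pick subject s minimising (key1, -gene width, gene_id)
    ord <- order(q, key1, -width(genes)[s],
                 as.character(mcols(genes)$gene_id)[s])
    keep <- ord[!duplicated(q[ord])]
    list(q = q[keep], s = s[keep])
  }

  hits <- GenomicRanges::findOverlaps(rloops, genes, ignore.strand = TRUE)
  if (length(hits)) {
    ov <- width(GenomicRanges::pintersect(rloops[queryHits(hits)],
                                          genes[subjectHits(hits)],
                                          ignore.strand = TRUE))
    best <- pick(queryHits(hits), subjectHits(hits), -ov)
    gene_id[best$q] <- as.character(mcols(genes)$gene_id)[best$s]
    txn[best$q] <- as.character(strand(genes))[best$s]
    assignment[best$q] <- "overlap"
  }
  todo <- which(assignment == "unassigned")
  if (length(todo) && length(genes)) {
    dtn <- GenomicRanges::distanceToNearest(rloops[todo], genes,
                                            ignore.strand = TRUE,
                                            select = "all")
    ok <- mcols(dtn)$distance <= max_dist
    if (any(ok)) {
      q <- todo[queryHits(dtn)[ok]]
      s <- subjectHits(dtn)[ok]
      best <- pick(q, s, mcols(dtn)$distance[ok])
      gene_id[best$q] <- as.character(mcols(genes)$gene_id)[best$s]
      txn[best$q] <- as.character(strand(genes))[best$s]
      assignment[best$q] <- "nearest"
    }
  }
  out <- rloops
  mcols(out)$gene_id <- gene_id
  mcols(out)$txn_strand <- txn
  mcols(out)$template_strand <- ifelse(is.na(txn), NA_character_,
                                       ifelse(txn == "+", "-", "+"))
  mcols(out)$assignment <- assignment
  out
}

# Classify each G4 peak by the strand(s) of QPS hits it overlaps (>= 1 nt):
# "none", "+", "-", or "both".
.g4_qps_strand <- function(g4_peaks, qps_hits) {
  p <- IRanges::overlapsAny(g4_peaks, qps_hits[strand(qps_hits) == "+"],
                            ignore.strand = TRUE)
  m <- IRanges::overlapsAny(g4_peaks, qps_hits[strand(qps_hits) == "-"],
                            ignore.strand = TRUE)
  ifelse(p & m, "both", ifelse(p, "+", ifelse(m, "-", "none")))
}

#' Classify G4 peaks near one oriented R-loop as template / non-template
#'
#' G4 peaks within `window` of the R-loop inherit the strand of the QPS
#' hit they overlap; a G4 whose QPS strand equals the R-loop's
#' transcribed strand sits on the displaced, non-template strand
#' (`strand_class = "non_template"`), otherwise on the template strand.
#' G4 peaks overlapping no QPS cannot be stranded and are dropped (their
#' count is reported); peaks overlapping QPS on both strands are flagged
#' ambiguous and kept out of either class.
#'
#' @param g4_peaks `GRanges` of G4 peaks.
#' @param qps_hits Stranded `GRanges` of QPS hits.
#' @param rloop A single oriented R-loop (one row of [orient_rloops()]
#'   output, with `txn_strand` set).
#' @param window Matching window around the R-loop (bp).
#' @return A `GRanges` of matched, stranded G4 peaks with metadata
#'   `qps_strand`, `strand_class` (`"non_template"`, `"template"` or
#'   `"ambiguous"`) and attribute `n_dropped_no_qps`.
#' @export
assign_g4_strand <- function(g4_peaks, qps_hits, rloop, window = 3000) {
  stopifnot(length(rloop) == 1)
  txn <- mcols(rloop)$txn_strand
  if (is.na(txn)) stop("R-loop is unassigned; orient it first")
  near <- g4_peaks[window_overlap(g4_peaks, rloop, window)$match]
  qs <- .g4_qps_strand(near, qps_hits)
  dropped <- sum(qs == "none")
  keep <- near[qs != "none"]
  qs <- qs[qs != "none"]
  mcols(keep)$qps_strand <- qs
  mcols(keep)$strand_class <- ifelse(qs == "both", "ambiguous",
                                     ifelse(qs == txn, "non_template",
                                            "template"))
  attr(keep, "n_dropped_no_qps") <- dropped
  keep
}

#' R-loop / G4 colocalization profile over increasing windows
#'
#' @param rloops Non-empty `GRanges` of R-loops.
#' @param g4_peaks `GRanges` of G4 peaks.
#' @param windows Ascending window sizes (bp).
#' @return data.frame with `window` and `fraction_with_g4` (monotone
#'   non-decreasing in `window`).
#' @export
colocalization_profile <- function(rloops, g4_peaks,
                                   windows = c(0, 1000, 3000, 10000)) {
  if (length(rloops) == 0) stop("empty R-loop set")
  if (is.unsorted(windows)) stop("windows must be ascending")
  frac <- vapply(windows, function(w)
    mean(window_overlap(rloops, g4_peaks, w)$match), numeric(1))
  data.frame(window = windows, fraction_with_g4 = frac)
}

#' Call G-loop-like structures
#'
#' For each oriented R-loop, G4 peaks within `window` are strand-classified
#' against the R-loop's transcribed strand (see [assign_g4_strand()]).
#' An R-loop with at least one non-template G4 in the window is
#' `gloop_like`; otherwise, one with at least one template G4 is
#' `template_g4`; otherwise `no_g4`. The signed distance of the nearest
#' class-defining G4 is reported in transcription coordinates (negative
#' upstream, 0 on overlap). Unassigned R-loops are excluded from the
#' stranded calls and counted in the summary.
#'
#' @param oriented Output of [orient_rloops()].
#' @param g4_peaks `GRanges` of G4 peaks.
#' @param qps_hits Stranded `GRanges` of QPS hits.
#' @param window Calling window (bp, default 3000).
#' @return List with `calls` (data.frame, one row per assigned R-loop)
#'   and `summary` (counts, category fractions, the non-template share
#'   among G4-associated R-loops, dropped / ambiguous G4 counts).
#' @export
call_gloops <- function(oriented, g4_peaks, qps_hits, window = 3000) {
  assigned <- which(!is.na(mcols(oriented)$txn_strand))
  rl <- oriented[assigned]
  qs_all <- .g4_qps_strand(g4_peaks, qps_hits)
  n_dropped <- sum(qs_all == "none")
  n_ambiguous <- sum(qs_all == "both")
  stranded <- g4_peaks[qs_all %in% c("+", "-")]
  qstr <- qs_all[qs_all %in% c("+", "-")]

  pairs <- window_overlap(rl, stranded, window)$pairs
  txn <- mcols(rl)$txn_strand[pairs[, "a"]]
  non_t <- qstr[pairs[, "b"]] == txn

  gap <- GenomicRanges::distance(rl[pairs[, "a"]], stranded[pairs[, "b"]],
                                 ignore.strand = TRUE)
  before <- end(stranded)[pairs[, "b"]] < start(rl)[pairs[, "a"]]
  after <- start(stranded)[pairs[, "b"]] > end(rl)[pairs[, "a"]]
  sgn_gen <- ifelse(before, -1L, ifelse(after, 1L, 0L))
  sdist <- gap * sgn_gen * ifelse(txn == "+", 1L, -1L)

  n <- length(rl)
  category <- rep("no_g4", n)
  signed_distance <- rep(NA_integer_, n)
  n_nt <- integer(n); n_t <- integer(n)
  if (nrow(pairs)) {
    n_nt <- as.integer(tabulate(pairs[non_t, "a"], n))
    n_t <- as.integer(tabulate(pairs[!non_t, "a"], n))
    category[n_t > 0] <- "template_g4"
    category[n_nt > 0] <- "gloop_like"
    # nearest class-defining G4 per R-loop
    use <- ifelse(category[pairs[, "a"]] == "gloop_like", non_t,
                  category[pairs[, "a"]] == "template_g4" & !non_t)
    if (any(use)) {
      ord <- order(pairs[use, "a"], gap[use])
      first <- ord[!duplicated(pairs[use, "a"][ord])]
      signed_distance[pairs[use, "a"][first]] <- sdist[use][first]
    }
  }
  calls <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rl)),
    start = start(rl), end = end(rl),
    gene_id = mcols(rl)$gene_id, txn_strand = mcols(rl)$txn_strand,
    category = category, signed_distance = signed_distance,
    n_non_template = n_nt, n_template = n_t,
    stringsAsFactors = FALSE)
  cnt <- c(gloop_like = sum(category == "gloop_like"),
           template_g4 = sum(category == "template_g4"),
           no_g4 = sum(category == "no_g4"))
  g4_assoc <- cnt[["gloop_like"]] + cnt[["template_g4"]]
  list(calls = calls,
       summary = list(
         n_total = length(oriented), n_assigned = n,
         n_unassigned = length(oriented) - n,
         counts = as.list(cnt),
         fractions = as.list(cnt / max(n, 1)),
         nontemplate_share = if (g4_assoc > 0)
           cnt[["gloop_like"]] / g4_assoc else NA_real_,
         n_g4_dropped_no_qps = n_dropped,
         n_g4_ambiguous = n_ambiguous,
         window = window))
}

#' Classify R-loops by resolution-failure category
#'
#' Per R-loop, four booleans are computed: `rnh1_bound` (>= 1 nt overlap
#' with RNase H1 peaks), `rnh1_lost` (>= 1 nt overlap with the
#' lost-in-condition differential set), `rpa32_present` (RPA32 peak within
#' `rpa32_window`, default 1 kb) and `hyperphos` (mean of the
#' phospho-RPA32 log2 rate track over the peak +/- `flank` exceeds
#' `theta`). Categories are assigned in order:
#' `a_lost_rpa_depleted` = lost and no RPA32;
#' `b_lost_hyperphos` = lost and hyperphosphorylated (not a);
#' `c_bound_hyperphos` = bound and hyperphosphorylated (not a, b);
#' `other` otherwise.
#'
#' @param rloops `GRanges` of R-loops.
#' @param rnh1_peaks,rnh1_lost,rpa32_peaks `GRanges` peak sets.
#' @param prate `binned_track` of log2(pRPA32/RPA32) rates.
#' @param theta Hyperphosphorylation threshold on the mean rate
#'   (default 0: phospho signal exceeds total after pseudocount).
#' @param flank Extension around the R-loop for the rate mean (bp).
#' @param rpa32_window RPA32 co-localization window (bp, default 1000).
#' @return List with `calls` (data.frame of booleans + `category`) and
#'   `frequencies` (named fractions over all R-loops, summing to 1).
#' @export
classify_resolution <- function(rloops, rnh1_peaks, rnh1_lost, rpa32_peaks,
                                prate, theta = 0, flank = 0,
                                rpa32_window = 1000) {
  chs <- unique(as.character(GenomeInfoDb::seqnames(rloops)))
  if (!all(chs %in% names(prate$values)))
    stop("rate track lacks chromosome(s): ",
         paste(setdiff(chs, names(prate$values)), collapse = ", "))
  rnh1_bound <- window_overlap(rloops, rnh1_peaks, 0)$match
  lost <- window_overlap(rloops, rnh1_lost, 0)$match
  rpa32_present <- window_overlap(rloops, rpa32_peaks, rpa32_window)$match
  hyperphos <- track_region_mean(prate, rloops, flank = flank) > theta
  category <- ifelse(lost & !rpa32_present, "a_lost_rpa_depleted",
              ifelse(lost & hyperphos, "b_lost_hyperphos",
              ifelse(rnh1_bound & hyperphos, "c_bound_hyperphos", "other")))
  lv <- c("a_lost_rpa_depleted", "b_lost_hyperphos", "c_bound_hyperphos",
          "other")
  calls <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rloops)),
    start = start(rloops), end = end(rloops),
    rnh1_bound = rnh1_bound, rnh1_lost = lost,
    rpa32_present = rpa32_present, hyperphos = hyperphos,
    category = factor(category, levels = lv), stringsAsFactors = FALSE)
  freq <- table(calls$category) / length(rloops)
  list(calls = calls, frequencies = as.numeric(freq) |>
         stats::setNames(lv))
}
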