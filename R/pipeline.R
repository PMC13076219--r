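#' Run the full analysis pipeline on a synthetic bundle
#'
#' Orchestrates every stage in dependency order: simulate the bundle
#' (genome, genes, peaks, tracks, read starts, FP titration), scan QPS
#' with G4Hunter, compute genome coverage percentages, build the
#' phospho-RPA32 rate track and the gamma-H2AX fingerprint, summarise
#' samples (Spearman/PCA), call differential DRIP regions, compute
#' fork-pausing enrichment and its overlap fractions, orient and call
#' G-loops with the colocalization profile, classify R-loop resolution
#' failure, and fit the FP isotherm. All intermediates are written in
#' standard formats under `out_dir` and a machine-readable `summary.json`
#' is emitted; rerunning with the same config reproduces it identically.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return A list of class `report_bundle`: `summary` (the summary list),
#'   `paths` (output files), plus the in-memory stage results.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("gloopr")) {
  stopifnot(inherits(config, "sim_config"))
  if (config$gloop_window < 0) stop("configuration error: negative window")
  bundle <- simulate_peaks_and_tracks(config)
  write_bundle(bundle, out_dir)
  p <- function(...) file.path(out_dir, ...)

  # --- QPS scan (G4Hunter) on the simulated genome
  qps <- g4hunter_call(bundle$genome, qps_params())
  write_qps_bed(qps, p("qps.bed"))

  # --- genome coverage percentages
  cov <- lapply(list(rloops_cond1 = bundle$rloops_cond1,
                     rloops_cond2 = bundle$rloops_cond2,
                     g4 = bundle$g4_peaks,
                     gamma_h2ax = bundle$gamma_h2ax,
                     rnh1_cond1 = bundle$rnh1_cond1,
                     rnh1_cond2 = bundle$rnh1_cond2),
                genome_coverage_percent, assembly = bundle$assembly)

  # --- tracks: pRPA32 rate, fingerprint, multi-sample summary
  prate <- log2_ratio(bundle$tracks$prpa32, bundle$tracks$rpa32,
                      pseudocount = 11)
  write_bedgraph(prate, p("tracks", "prpa32_rate.bedgraph"),
                 keep_zero = TRUE)
  fp_gamma <- fingerprint(bundle$tracks$gamma)
  summ <- sample_summary(unname(bundle$tracks), bin_size = 10000,
                         ntop = 1000)

  # --- differential DRIP regions
  diff <- bdgdiff_call(bundle$tracks$drip1, bundle$tracks$drip2,
                       diff_params())
  if (length(diff)) {
    out <- diff
    mcols(out) <- S4Vectors::DataFrame(
      name = mcols(diff)$direction,
      score = round(1000 * pmin(mcols(diff)$peak_llr, 10) / 10))
    write_intervals(out, p("diff_regions.bed"))
  }

  # --- fork pausing enrichment and overlap fractions
  tr <- trael_enrichment(bundle$trael$day3, bundle$trael$day0)
  frac_gamma_trael <- overlap_fraction(bundle$gamma_h2ax, tr$enriched, 0)
  frac_trael_rloop <- if (length(tr$enriched))
    overlap_fraction(tr$enriched, bundle$rloops_cond1_specific, 0)
    else NA_real_

  # --- G-loop calling and colocalization
  oriented <- orient_rloops(bundle$rloops_cond1, bundle$genes,
                            max_dist = 3000)
  gl <- call_gloops(oriented, bundle$g4_peaks, qps,
                    window = config$gloop_window)
  utils::write.table(gl$calls, p("gloop_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  coloc <- colocalization_profile(bundle$rloops_cond1, bundle$g4_peaks)

  # --- resolution classification
  res <- classify_resolution(bundle$rloops_cond1, bundle$rnh1_cond1,
                             bundle$rnh1_lost, bundle$rpa32, prate,
                             theta = 0, flank = 0, rpa32_window = 1000)
  utils::write.table(res$calls, p("resolution_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- FP isotherm fit
  fp_fit <- fit_isotherm(bundle$fp$data$P_T, bundle$fp$data$FP,
                         L_T = config$fp$L_T)

  summary <- list(
    seed = config$seed,
    coverage_percent = cov,
    n_qps_hits = length(qps),
    colocalization = stats::setNames(as.list(coloc$fraction_with_g4),
                                     paste0("w", coloc$window)),
    gloop = gl$summary,
    resolution_frequencies = as.list(res$frequencies),
    n_differential_regions = length(diff),
    n_differential_cond1 = sum(mcols(diff)$direction == "cond1"),
    trael = list(n_enriched = length(tr$enriched),
                 frac_gamma_overlapping_enriched = frac_gamma_trael,
                 frac_enriched_overlapping_rloops = frac_trael_rloop),
    fingerprint_auc_gamma = fp_gamma$auc,
    fp_fit = list(K_D = fp_fit$K_D, F_L = fp_fit$F_L, F_LP = fp_fit$F_LP,
                  converged = fp_fit$converged))
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  structure(list(summary = summary, out_dir = out_dir, bundle = bundle,
                 qps = qps, prate = prate, diff = diff, trael = tr,
                 oriented = oriented, gloops = gl, coloc = coloc,
                 resolution = res, fp_fit = fp_fit,
                 sample_summary = summ),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle (seed ", x$summary$seed, ") in ", x$out_dir, "\n",
      sep = "")
  cat("  QPS hits:", x$summary$n_qps_hits,
      "| differential regions:", x$summary$n_differential_regions,
      "| TrAEL enriched:", x$summary$trael$n_enriched, "\n")
  cat("  G-loop non-template share:",
      round(100 * x$summary$gloop$nontemplate_share, 1), "%\n")
  invisible(x)
}
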