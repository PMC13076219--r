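---
title: "Methods: strand-aware G-loop calling, differential enrichment, and binding isotherms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strand-aware G-loop calling, differential enrichment, and binding isotherms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and scientific background

R-loops are three-stranded structures in which a nascent transcript stays
hybridised to its template DNA strand, displacing the non-template strand
as single-stranded DNA. When that displaced strand is guanine-rich it can
fold into a G-quadruplex (G4); the composite structure -- an R-loop with a
G4 on the displaced, non-template strand -- is a *G-loop*. G-loops resist
RNase H1, the ribonuclease that normally removes DNA:RNA hybrids, and
their genomic accumulation is linked to replication stress and
oncogene-induced senescence.

`gloopr` implements the genome-arithmetic pipeline needed to identify
G-loop-like loci from peak sets and signal tracks, plus the two
quantitative models used around it: a Poisson likelihood-ratio caller for
differential enrichment between conditions, and the exact
(ligand-depletion) binding isotherm used to estimate dissociation
constants from fluorescence polarization titrations. Because the original
sequencing data are not packaged, every stage is validated against a
seedable synthetic-data generator with machine-readable planted truth.

# Data model

Intervals are `GRanges` (Bioconductor 1-based, closed); assemblies are
`Seqinfo`; sequence is `DNAStringSet`. On disk the package speaks the
0-based half-open BED family (BED3/6/12, narrowPeak, bedGraph, two-column
chrom.sizes, 60-column FASTA), with reading and writing delegated to
`rtracklayer` and `Biostrings`; conversion between conventions happens at
the file boundary and nowhere else. Binned signal is a `binned_track`:
fixed-width per-chromosome numeric vectors plus the library size used for
normalisation.

Two interval conventions matter throughout and follow the `bedtools`
family, since that is what published workflows of this kind sit on:

* **Window matching** (`window_overlap()`): intervals match iff they share
  at least one nucleotide, or the gap between nearest edges is *strictly
  less* than the window. A window of 0 is plain overlap; book-ended
  intervals do not match at window 0 but do at any positive window. The
  underlying publications never state whether "within 3 kb" is
  edge-to-edge or centre-to-centre; we use the edge gap (the `windowBed`
  convention) and expose the window as a parameter everywhere.
* **Merging** (`merge_intervals()`): strand-blind union; book-ended
  intervals merge, matching `bedtools merge` defaults.

Feature annotation assigns each peak exactly one category by the position
of its midpoint, with priority promoter > TSS > TES > exon > intron >
intergenic and promoter = [TSS − 2000, TSS + 500) in transcription
coordinates. Midpoint assignment (rather than any-overlap) makes the
category distribution a partition that sums to 100%.

# QPS prediction

Quadruplex-forming sequences (QPS) are predicted two ways.

**G4Hunter scoring.** Each base in a maximal run of *n* guanines scores
+min(*n*, 4); cytosine runs score the negative; A, T and N score 0 (N
breaks runs, so assembly gaps never nucleate calls). The mean score over
25-base windows is thresholded at |mean| ≥ 1.2 -- the word size and
threshold used in the source analyses. Overlapping or adjacent
above-threshold windows of the same sign are merged, the merged span is
trimmed to begin and end on a scoring base (G for +, C for −), and the
mean is recomputed over the trimmed span. Merging can occasionally dilute
the recomputed mean below threshold; in that case the hit falls back to
the strongest single window, which keeps the reported-score invariant
(|mean| ≥ threshold) intact. Hit strand is the score sign: a positive
window is a G4 on the given strand, a negative one on its complement.

**QGRS-style enumeration.** Motifs `G{g} L1 G{g} L2 G{g} L3 G{g}` with
g ≥ 2, loop lengths 0--36 and total length ≤ 30 are enumerated exhaustively
(a small C++ kernel) on both strands; both the loop and length constraints
are enforced literally as published, so the length cap is what binds in
practice. The original G-score ranking formula is not public; overlapping
candidates are resolved by a documented deterministic rule instead --
larger g, then shorter total length, then leftmost start. This is a
stand-in ranking, not a reconstruction of the original.

# Signal tracks

Coverage is binned at 50 bp by default. Interval inputs are counted by
fractional bin occupancy (deterministic and exactly conservative:
Σ bins × bin size = total base overlap); width-1 read-start inputs are
counted integrally. RPM is `count * 1e6 / library`; RPKM additionally
divides by bin size in kb. Rate tracks are per-bin
`log2((a + pc) / (b + pc))`; the phospho-RPA32 rate uses pseudocount 11 on
50 bp bins, the (unusual) published setting, honoured verbatim rather than
reinterpreted. Reference-point matrices average track signal in columns
around interval midpoints, reversing columns for minus-strand anchors in
strand-oriented mode; out-of-chromosome spans contribute zero and are
flagged. The fingerprint curve is the Lorenz curve of bin values
(ascending sort, cumulative fraction), whose area is 0.5 for perfectly
uniform signal. Multi-sample summaries rebin to 10 kb by averaging,
compute Spearman correlations over all shared bins, and run PCA (SVD of
the centered sample-by-bin matrix) on the 1000 most variable bins;
component signs are arbitrary and all tests are sign-invariant.

# Differential calling and fork-pausing enrichment

The per-bin statistic is the signed log10 Poisson likelihood ratio: for
scaled counts with pseudocount applied, magnitude
`(x ln(x/y) + y − x) / ln 10` with x = max, y = min. Tracks are scaled to
the smaller of the two configured depths (defaults 14 and 14, in
millions), a pseudocount of 1 is added, and maximal bin runs beyond the
cutoff -- bridging internal gaps up to 100 bp -- are emitted if at least
200 bp long. Defaults (cutoff 0.5, min-len 200, max-gap 100) follow the
published caller flags. Two published statements are mutually
inconsistent and are surfaced rather than resolved: a log10 cutoff of 0.5
is described as "a likelihood ratio of 500" (10^0.5 ≈ 3.16), and the
minimum length appears both as 200 bp (flag) and 50 bp (text); the
implementation takes the flag values and makes both configurable.

Fork-pausing enrichment quantifies 3'-end read starts in 50 kb bins,
RPM-normalises each sample, and reports bins whose day3/day0 ratio is at
least 1.5, merged when adjacent. The ratio is left undefined (and the bin
excluded) where the day0 signal is below 1 RPM, a floor the source never
states but which prevents division blow-ups.

Under the generator's independent per-bin Poisson model the exact tail
probabilities at depth 50 and fold 1.5 are: recall of 2x bins ≈ 95.8%
(dropping toward ~95.4% as planted bins inflate the day-3 library), and a
false-positive rate of ≈ 2.45% per bin. The latter is an intrinsic
property of the ratio test at this depth: a 1% false-positive expectation
is not achievable without deeper coverage or a different statistic, and
the acceptance suite records this honestly rather than adjusting the
conditions.

# G-loop calling

R-loops are oriented by transcription: each peak is assigned to the gene
with the largest base overlap, falling back to the nearest gene within
3 kb, with deterministic tie-breaks (larger overlap, longer gene,
lexicographic id). The displaced strand of an R-loop is the non-template
(coding) strand of its gene. G4 peaks near an R-loop inherit the strand
of the QPS hit they overlap; a QPS on the transcribed strand means the G4
sits on the displaced strand, hence `non_template`. G4 peaks with no
overlapping QPS cannot be stranded and are dropped (counted); peaks with
QPS on both strands are reported as an ambiguous class rather than forced
into either. An R-loop with a non-template G4 within the 3 kb calling
window is `gloop_like`; otherwise a template G4 within the window makes it
`template_g4`; otherwise `no_g4`. Signed distances are edge gaps in
transcription coordinates, negative upstream, zero on overlap. The 10 kb
colocalization profile is reported alongside but never used for calling.

Resolution-failure classification computes, per R-loop: RNase H1 overlap
(≥ 1 nt), membership in the lost-in-condition differential set, RPA32
co-localization within 1 kb, and hyperphosphorylation (mean of the
log2 pRPA32/RPA32 rate over the peak above θ). Categories are assigned
with fixed precedence: (a) lost and RPA32-depleted, (b) lost and
hyperphosphorylated, (c) bound and hyperphosphorylated, else other. The
publications show rate metaplots but never a binary threshold; θ defaults
to 0 on the log2 scale (phospho exceeds total after the pseudocount) with
flank 0, both configurable.

# Binding model

Polarization is `FP = 1000 (S − G·P) / (S + G·P)`; the instrument G
factor is determined from a probe-only well by inverting that equation at
a nominal free-probe polarization (default 0 -- the source says the factor
was determined from the probe alone without giving the reference value,
so it is exposed as a parameter). The titration model is the exact 1:1
isotherm with ligand depletion,

F = F_L + (F_LP − F_L) · [ (L_T + P_T + K_D) − sqrt((L_T + P_T + K_D)^2 − 4 L_T P_T) ] / (2 L_T),

which reduces to the hyperbola when L_T ≪ K_D. Fitting is unweighted
least squares in (log K_D, F_L, F_LP) with L_T fixed: the log
parameterisation enforces positivity and conditions the problem; starting
values are the geometric mean of the protein grid and the observed
min/max polarization. Standard errors come from the local curvature, with
K_D's by the delta method. A fit is reported non-converged when the
optimiser fails or when se(log K_D) ≥ 1 -- i.e. the data do not determine
K_D within a factor of e -- which catches flat curves and grids far below
K_D without throwing. The default titration mirrors the published design:
probe at 30 nM, protein 0.03--30 uM.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the tests exercise, chosen once:

* genome: chr1 = 1.5 Mb + chr2 = 0.5 Mb of i.i.d. ACGT at GC 0.5;
* genes: 80 non-overlapping, strands Bernoulli(0.5), lengths 2--20 kb
  (published-scale gene lengths of up to 50 kb cannot be packed without
  overlap into a 2 Mb desk-scale genome, so the range was narrowed once
  and made configurable), with alternating exon/intron blocks;
* R-loops: 500 per condition, widths 200--2000 bp, anchored in gene
  bodies; 40% condition-specific;
* planted QPS: 79% of oriented R-loops get a non-template-strand motif
  within 3 kb and 21% a template-strand motif upstream, mirroring the
  reported split; motifs are four G4 tracts with 1--7 nt A/T loops,
  verified to reach a G4Hunter window mean of 1.3 (above the 1.2 calling
  threshold, so planted recall is guaranteed by construction rather than
  probabilistically);
* tracks: Poisson counts per 50 bp bin at baseline rate 2, multiplied by
  5 inside peaks; phospho-RPA32 runs at 0.5x the RPA32 rate outside and
  3x inside hyperphosphorylated R-loops, so the rate track separates
  cleanly at θ = 0;
* resolution categories planted at the reported frequencies
  (8.3 / 5.2 / 43.1% and the remainder);
* differential pairs: 20 planted 1-kb regions at 3x a pileup-scale
  baseline of 10 counts per 50 bp bin (condition 2 stays at baseline);
* read starts: day0 Poisson(50) per 50 kb bin, planted pausing bins at
  twice the rate;
* FP titrations: K_D 150 nM, probe 30 nM, 12 log-spaced protein points
  over 0.03--30 uM, 1% multiplicative Gaussian noise.

All draws derive from per-component substreams of one master seed, so
regenerating with the same seed is byte-identical and adding a component
does not shift the others.

Two geometries serve different purposes. The *bundle*
(`simulate_peaks_and_tracks()` + `run_pipeline()`) packs everything onto
the 2 Mb genome at realistic density; there, planted configurations
interact (a template-planted R-loop can sit within 3 kb of a neighbour's
non-template motif), so the bundle validates orchestration, format
round-trips and internal consistency -- not truth recovery. The *cohorts*
(`simulate_gloop_cohort()`, `simulate_coloc_cohort()`,
`simulate_resolution_cohort()`) give each R-loop its own spaced territory
sized beyond the largest test window, which makes the planted categories
geometrically clean and exactly recoverable; their genome size scales
with n. Recovery tolerances are pre-registered (±3 percentage points for
category splits; binomial 99% intervals for colocalization fractions).
One further cleanliness device matters: background sequence at GC 0.5
produces G4Hunter hits at threshold 1.2 about once per kilobase, so the
flanks of each planted motif are neutralised to A/T -- otherwise a
jittered G4 peak can overlap an opposite-strand background window and
become ambiguous through no fault of the caller.

What the generator does *not* emulate: real genome sequence composition
(repeats, CpG islands, isochores), read-level artifacts (fragment-size
and GC bias, duplicates), overdispersed counts (noise is Poisson by
design, matching the caller's model so oracle tests are exact), and
correlated neighbouring bins. Passing tests therefore demonstrate the
correctness of the computations, not the biological error rates to expect
on real libraries; in particular the iid-Poisson noise makes the
differential caller emit more small spurious regions than it would on
smooth real pileups, and the recovery criteria deliberately score only
the planted regions.

# Numerical choices and degenerate inputs

* Bin values are means over full bins; a chromosome's trailing partial
  bin is treated as if it had full width, which keeps
  signal-conservation identities exact on aligned boundaries.
* `log2_ratio` with pseudocount 0 refuses denominators containing zero
  bins rather than emitting infinities.
* `poisson_log10_lr` is exactly antisymmetric and returns 0 on ties; a
  zero count against a positive one gives +/-Inf, which the pseudocount
  (default 1) prevents in the caller.
* Empty peak sets: coverage percent is 0; `overlap_fraction` and
  `colocalization_profile` refuse empty query sets (a fraction of nothing
  is undefined, not zero).
* All randomised tie-breaks were replaced by deterministic orderings
  (documented per function) so reruns are bit-identical.

# Problem sizes used by the tests

Unit tests run on genomes of 0.2--0.6 Mb and cohorts of 100--300 loci;
the recovery suite uses the pre-registered sizes (1000 R-loops for the
G-loop and resolution cohorts, 500 for colocalization, 20 planted
differential regions, 60,000 TrAEL bins, 100 Monte-Carlo titrations); the
end-to-end run uses the default 2 Mb bundle. These sizes were chosen so
the whole suite completes in a few minutes on one core while keeping
binomial noise well inside the pre-registered tolerances.

# Known limitations

* QGRS ranking is a documented stand-in for the unpublished G-score.
* The G4Hunter merged-region refinement is an interpretation (trim to
  scoring-base boundaries); the original tool's exact region output is
  not specified in the sources we follow.
* The differential caller models replicates by summed pileups, not a
  dispersion model; it is a region screen, not an FDR-controlled test.
* bigWig is not read or written; bedGraph is the interchange format.
* The fork-pausing false-positive rate at depth 50 is bounded below by
  the Poisson ratio-test tail (~2.4% at fold 1.5), as discussed above.
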