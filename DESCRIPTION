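Package: gloopr
Title: Strand-Aware Calling of G-Loop Structures from R-Loop and
    G-Quadruplex Genomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to identify G-loop-like structures, defined as R-loops
    co-occurring with a G-quadruplex folded on the displaced (non-template)
    DNA strand. Provides G4Hunter window scoring and QGRS-style motif
    enumeration for quadruplex-forming sequence prediction, transcription-
    direction orientation of DRIP-seq R-loop peaks, template versus
    non-template strand classification of G4 evidence, binned signal tracks
    with RPKM/RPM normalisation, log2 ratio tracks, reference-point signal
    matrices and metaplots, fingerprint (Lorenz) curves, Poisson
    log-likelihood-ratio differential region calling, replication fork
    pausing enrichment from 3'-end sequencing read starts, a three-category
    classification of R-loop resolution failure, and quadratic
    ligand-depletion fitting of fluorescence polarization binding isotherms.
    A seedable synthetic-data generator with machine-readable ground truth
    supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
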