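Package: ribopause
Title: Read-Length-Stratified Ribosome Profiling Analysis of Codon-Specific
    Pausing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects codon-specific ribosome pausing from ribosome profiling
    (Ribo-seq) footprints stratified by read length. Short (~21 nt) footprints
    arise from ribosomes with an open A-site awaiting aminoacyl-tRNA delivery;
    long (~29 nt) footprints from post-accommodation ribosomes, so
    length-resolved A-site codon occupancy separates pre- from
    post-accommodation pausing. Provides transcript-space footprint I/O,
    P-site offset calibration from start-codon metagene profiles, 3-nt
    periodicity QC and periodic-length selection, per-codon A-/P-site
    occupancy tables normalized within (site, read length, sample) strata,
    replicate-averaged between-condition frequency ratios, and a two-state
    codon dwell-time footprint simulator with ground truth and an analytic
    occupancy oracle for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    Rsamtools,
    ggplot2,
    jsonlite,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
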