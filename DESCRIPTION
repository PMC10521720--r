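Package: ramansip
Title: Single-Cell Raman Stable-Isotope-Probing Analysis and Contig Binning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-cell Raman stable-isotope-probing (Raman-SIP)
    studies of CO2-fixing bacteria. Simulates carotenoid resonance Raman
    spectra under 13C-bicarbonate labeling, preprocesses raw spectra
    (despiking, fluorescence baseline removal, smoothing, normalization),
    fits the carotenoid nu1/nu2 bands and quantifies their isotope-induced
    red shifts, classifies cells by a simultaneous two-band shift criterion
    as used for Raman-activated cell sorting, summarizes labeling time
    courses with steady-state detection, and bins assembled contigs by
    canonical tetranucleotide composition with GC and purity reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    minpack.lm,
    Matrix,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
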