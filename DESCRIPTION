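Package: msnoise
Title: Locally Adaptive Noise Filtering for Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Noise filtering for peptide MS/MS peak lists. Estimates a local
    noise level in equally spaced m/z bins using a sorted-intensity
    signal-to-noise stopping rule with rank regression, then smooths the
    per-bin levels into a continuous noise curve by least squares on
    Gram-Chebyshev orthogonal polynomials for equally spaced points. Includes
    the global SNR filter and a lower-half-median baseline for comparison, a
    top-percent baseline, theoretical b/y/a fragment-ion generation with
    water and ammonia losses, peak classification against a known peptide,
    signal-retention reporting, a mass-position-aware amino-acid match score
    for de novo sequence evaluation, and a ground-truth synthetic spectrum
    simulator. Readers and writers for MGF and two-column peak-list TSV are
    provided, with optional mzML input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    mzR
Config/testthat/edition: 3
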