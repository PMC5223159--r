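Package: matriquant
Title: Quantitative Matrisome Profiling from Isobaric-Label Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for iTRAQ 4-plex quantitative profiling of
    extracellular-matrix (matrisome) proteins across staged tumor progression.
    Filters peptide-spectrum matches by label, identification-confidence and
    precursor-purity rules, rolls reporter-ion ratios up to protein-level log2
    ratios by the median, normalizes each channel by the matrisome-protein
    median, tests for non-zero log-ratios across time points with a from-scratch
    empirical-Bayes moderated F-test, annotates proteins against a bundled
    matrisome reference, derives a normal-tissue matrisome membership set with a
    precursor-weighted relative-abundance ranking, and ships a synthetic
    peptide-spectrum-match generator with planted ground truth, including a
    co-isolation ratio-compression model, so the whole pipeline is testable
    without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    tools,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    pheatmap
Config/testthat/edition: 3
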