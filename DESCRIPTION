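Package: dialyspep
Title: Paired Differential Peptidomics of Brain Microdialysate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of label-free peptidomic quantification tables from paired
    (within-subject) microdialysis experiments, as used to profile extracellular
    peptide changes during 4-aminopyridine-induced epileptic seizures. Implements
    two-stage abundance normalization (total-intensity then stable-reference-peptide),
    missingness filtering, presence/absence treatment markers, paired t-tests with
    Benjamini-Hochberg adjustment and fold-change gating, peptide positional
    annotation (terminal-fragment classes, N-terminal acetylation, cleavage-site
    residue contexts and frequency matrices, dibasic flanks, domain overlaps),
    sample embedding and four-algorithm consensus feature selection, and an EEG
    spectral module (FFT low-pass, Welch/Hanning power spectra, band-area
    integration, paired band-power comparison). A synthetic-data generator emulates
    the full data structure - peptidome, paired abundances, left-censored
    missingness, EEG traces - with a ground-truth ledger so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    glmnet,
    randomForest,
    ranger,
    e1071,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
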