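Package: ramahet
Title: Deciphering Spectral Heterogeneity in Fresh Tissue Raman Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A histology-independent workflow for decomposing the spectral
    heterogeneity of fresh glioblastoma Raman measurements. Raw spectra are
    cleaned (cosmic-ray removal, iterative Savitzky-Golay baseline and
    fluorescence subtraction, two-stage standardization) and screened for
    strong outliers with an agglomerative-clustering QC scan. A random-forest
    classifier with patient-wise splitting and repeated, patient-grouped
    internal cross-validation separates spectroscopically necrotic from vital
    tumor tissue; its f1-optimal decision threshold re-labels the whole data
    set into a "spectral vital" subset. That subset is decomposed by k-means
    with WSS-based selection of the cluster count, visualized with UMAP, and
    healthy-control spectra are assigned to the discovered clusters by
    nearest-centroid similarity. A multi-patient synthetic Raman cohort
    generator with known ground truth (tissue-class peak profiles, per-patient
    batch effects, fluorescence background, acquisition-time-dependent noise,
    cosmic rays and hot pixels) supports validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    uwot,
    signal,
    jsonlite,
    pROC,
    withr
Suggests: testthat (>= 3.0.0), cluster, mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
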