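---
title: "Deciphering spectral heterogeneity in fresh tissue Raman measurements"
author: "ramahet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciphering spectral heterogeneity in fresh tissue Raman measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Glioblastoma is a spatially heterogeneous brain tumor: a single fresh
surgical specimen can contain vital tumor tissue, necrosis, infiltrated
brain and peritumoral gray or white matter, entangled at millimeter scale.
Raman spectroscopy reads a molecular fingerprint off fresh tissue in
seconds, but the histopathological label attached to a specimen describes
the *specimen*, not each measured spot. `ramahet` implements a
histology-independent, two-step computational decomposition of such data:

1. **Supervised step.** A binary random-forest classifier learns the
   spectral fingerprint of necrosis from the specimens whose histology is
   unambiguous (mostly-necrotic vs vital/infiltrative). Its f1-optimal
   decision threshold, derived purely from internal cross-validation, then
   re-labels *every* tumor spectrum by its spectral properties alone. The
   non-necrotic remainder is the *spectral vital* data set.
2. **Unsupervised step.** The spectral vital set is decomposed by k-means
   (Euclidean distance in the standardized spectral feature space) with the
   cluster count chosen from a within-cluster sum-of-squares (WSS) scan,
   and displayed with an independently computed UMAP embedding. Healthy
   autoptic gray- and white-matter spectra are afterwards assigned to the
   discovered clusters by nearest-centroid similarity, anchoring some
   clusters to non-tumorous tissue; overlap of histology tags (e.g.
   infiltration zone) with those clusters is reported as simple count
   bookkeeping.

The two views — classifier-driven probability overlay and k-means
partition — are computed independently and only combined for display, so
their agreement acts as a control against computational artifacts.

# Data model

A `SpectraSet` (a `SummarizedExperiment` subclass) holds an
`intensity` assay of frequency bins x spectra on one shared
`WavenumberGrid`, per-spectrum metadata (patient, specimen, histological
class among necrosis / vital / heterogeneous / control gray / control
white, free-form tags, acquisition time, number of co-added acquisitions)
and a provenance log of the processing steps applied. The default grid is
400–1800 cm⁻¹ in 1024 bins: the biological fingerprint region at the
resolution of a typical 1024-pixel CCD, which keeps even narrow tissue
bands (sigma ≥ 5 cm⁻¹) several bins wide — a requirement for the
single-bin artifact detector below.

# Preprocessing

The canonical order is `removeCosmicRays()` → `baselineCorrect()` →
`standardizeSpectra()`; the provenance log records it and re-running a
step warns.

**Cosmic rays and hot pixels** are single-bin events. A bin is flagged
when its residual against a 5-bin running median exceeds `z = 8` times a
robust per-spectrum noise floor, and is replaced by the running-median
value. The noise floor is the MAD of first differences divided by √2
rather than the MAD of the running-median residuals themselves: on a
sloped fluorescence background the running-median residuals are exactly
zero wherever the window is monotone, which collapses their MAD and would
flag ordinary noise. At `z = 8` the false-positive rate on spike-free
Gaussian noise is negligible while genuine spikes (≥ 10x the strongest
band) and saturated pixels sit orders of magnitude above the cut.

**Baseline and fluorescence removal** uses an iterative Savitzky–Golay
scheme (window 101 bins, order 3, 10 fixed iterations): smooth, clamp the
working curve to the smooth from above (suppressing peaks), re-smooth;
the final smooth is subtracted. The original measurements were
baseline-corrected on the instrument; this re-implementation is a
functional, not bit-exact, equivalent so that raw synthetic spectra can
be processed. Small negative residuals are retained — the subsequent
standardization makes the sign irrelevant. The window must dwarf the
Raman line width (here ≥ 20x) yet track the background; 101 bins ≈ 138
cm⁻¹ satisfies both for the default grid.

**Standardization** is two-stage: first each spectrum is centered and
scaled to unit sd across its bins (standard normal variate, which removes
per-acquisition gain and offset — including the simulated per-patient
multiplicative batch effect); then each frequency bin is centered and
scaled to unit sd across spectra. The order (spectrum first, then bin) is
fixed and documented; the bin means and sds are stored so that external
spectra — validation and healthy controls — can be mapped into the *same*
feature space with `applyStandardization()`, never refit. Stage-2 column
statistics are exactly (0, 1) and are asserted as such in the tests.
Constant spectra cannot be SNV-scaled and are dropped with a warning.

**QC scan.** Ward-linkage agglomerative clustering on Euclidean
distances; the top three split levels of the dendrogram are summarized
and a spectrum is flagged as a strong outlier if it sits in a branch
smaller than max(2, 0.5 % of n) at any of those levels. The flag
threshold is a package choice (the original screen was visual); it is
exposed as a parameter.

# The necrosis/vital classifier

Patients — never spectra — are assigned to exactly one of the
train/validation splits (`splitPatientwise()`), and each patient
contributes at most 15 spectra per class, limiting patient-specific
weight. Internal cross-validation (5 splits, repeated 3 times) is
*patient-grouped and stratified*: a patient's spectra never straddle a
fold boundary, otherwise patient identity leaks into the internal
estimate. When the patient count cannot support a fold geometry with both
classes on each side, the fold count is reduced with a warning.

Hyperparameters (trees 100/500, depth unlimited/20, mtry √p / 0.1 p) are
chosen by mean internal f1 of the necrosis class; the final forest is
refit on all training spectra with impurity importance. The model's score
is always the probability of *necrosis*; the orientation is recorded in
the object to prevent silent flips.

The decision threshold maximizes the f1 score of the necrosis class over
the pooled out-of-fold scores; candidates are the midpoints between
consecutive distinct scores plus 0 and 1, and ties break toward the lower
(more necrosis-sensitive) threshold. Spectra scoring exactly the
threshold are called necrotic. A threshold of 0 or 1 is degenerate but
representable (it arises under label permutation); all-equal scores
return 0.5 with a warning. `evaluateModel()` refuses any validation set
sharing a patient with training.

The metric panel reports per class (with that class as positive) AUROC,
AUPR (step-integrated average precision), precision, recall, f1 and the
*misclassification ratio*, defined here as the per-class error rate
1 − recall — the reading consistent with a 76 % accuracy arising from
error rates 0.15/0.31 on validation supports of 40/45. Macro and
support-weighted averages complete the panel.

# Heterogeneity decomposition

`relabelSpectra()` scores the whole tumor set (healthy controls are
excluded by construction) and splits it at the stored threshold;
`subsamplePerPatient()` then caps each patient at 30 spectra before the
unsupervised stage. The cap is 30 rather than the classifier's 15
because the spectral-vital stage pools all histological classes per
patient; both caps are exposed.

`wssCurve()` records, for K = 1..50, the inertia of the best of 10
k-means runs with k-means++ seeding (`stats::kmeans` is the engine; the
seeding is implemented in the package since the stock implementation
offers only random starts). Each K additionally warm-starts from the
previous K's centers plus the worst-fit point; since k-means only ever
decreases its objective from an initialization whose inertia is already
≤ WSS(K−1), the curve is non-increasing *by construction*, not merely in
expectation. WSS(1) equals the total sum of squares and WSS(n) = 0.

`selectK()` operationalizes the verbal majority criterion — few clusters
hold the bulk, enough clusters remain for rare subgroups — as: the
smallest K, **at or beyond the WSS elbow**, for which (a) the largest 7
clusters jointly hold ≥ 90 % of the spectra and (b) at least 3 clusters
smaller than 10 spectra exist. The elbow floor (maximum perpendicular
distance to the chord of the WSS curve) is essential: without it the
criterion with `min_minor_clusters = 0` is satisfied by K = 1 for any
data, since the "top 7" of a single cluster trivially covers everything.
With the floor, well-separated planted structures are recovered at their
natural K and the degenerate single-blob case falls back to the elbow
with a warning. All three constants are configurable.

`fitClusters()` runs k-means at the selected K **in the standardized
spectral feature space, never on the UMAP coordinates** — the embedding
is a display device, and reclustering an embedding would make the two
views circular. After fitting, every spectrum is re-assigned to its
nearest centroid with ties broken toward the lower cluster id, and
clusters are renumbered by decreasing size (cluster 1 is the largest).
The taxonomy calls clusters of ≥ 10 spectra *major*, 2–9 *small* and 1
*singleton*; coverage is the share of spectra in major clusters.

`assignExternal()` standardizes control spectra with the stored training
bin statistics and assigns each to its nearest centroid; per control
class the distribution over clusters is reported as counts and integer-
rounded percentages (85 % = round(100·47/55)). `overlapReport()` counts,
per histology tag, the tagged spectra per cluster and the fraction inside
a designated cluster set — pure bookkeeping, and asserted as such against
worked examples in the tests.

UMAP runs with n_neighbors = 15, min_dist = 0.1, Euclidean metric and a
fixed seed (single-threaded, so coordinates are bit-reproducible); none
of these values is data-derived.

# The synthetic cohort generator

The study's patient spectra are not publicly deposited, so `ramahet`
ships a generator whose default preset mirrors the cohort the pipeline
is designed for: 43 tumor patients, 1456 tumor spectra labeled 81
necrosis / 1304 vital / 71 heterogeneous, plus one autoptic case with 55
gray- and 32 white-matter control spectra. Necrotic spectra concentrate
in 11 patients, mirroring the class imbalance of the supervised task.

Each tissue profile is a sum of Gaussian bands on a decaying-exponential
fluorescence background, built on well-known Raman bands of brain tissue
(phenylalanine 1004 cm⁻¹, lipid 1064/1296/1438 cm⁻¹, amide I ~1660
cm⁻¹, heme 754/1588 cm⁻¹, bone mineral 960 cm⁻¹, ...). Eleven
non-necrotic profiles are planted: five vital-tumor subtypes, gray and
white matter (appearing both as infiltrated tumor tissue, tagged
`infiltration_zone`, and as the healthy controls), and four rare
contaminants (blood 8, bone 5, charred tissue 3, foreign body 1 spectra)
that seed small clusters and singletons. Gaussian line shapes suffice
because no downstream step exploits the line shape; a single exponential
background suffices because the baseline step only requires a smooth,
broad nuisance component.

Per patient, one multiplicative gain (log-normal, sd 0.15 on the log
scale) and one global wavenumber shift (normal, sd 1 cm⁻¹) are drawn
once — the minimal batch-effect model the QC/confounder machinery must
be able to interrogate. Detector noise is Gaussian with sd
`noise_sd_base/√t` for acquisition time t drawn from the instrument's
0.7–10 s regime (`noise_sd_base = 0.6` intensity units); cosmic rays
(rate 0.04/spectrum, single-bin, ≥ 10x the strongest band) and a fixed
saturated hot pixel (rate 0.01) complete the artifact model. Everything
is reproducible from one integer seed.

**What the generator does not emulate:** real tissue autofluorescence
shape variation, wavenumber-dependent instrument response, detector
etaloning, water/substrate bands, spatial correlation between
measurement spots of one specimen, and — most importantly — the
continuous biochemical gradients between tissue types. Planted profiles
are discrete; real "heterogeneity" is partly continuous. Passing the
recovery tests therefore shows the pipeline's machinery is correct and
well-calibrated, not that real glioblastoma decomposes into exactly
these clusters.

# Numerical choices and degenerate inputs

* Seeds: every stochastic stage takes an explicit seed; the pipeline
  derives stage seeds from one master seed by fixed small offsets.
* k-means ties (equidistant centroids) break toward the lower cluster
  id; with fewer distinct points than K, a closed-form degenerate
  solution keeps the convention (all identical points land in cluster 1).
* WSS monotonicity is guaranteed by warm starting, so the invariant is
  asserted at 1e-6 relative tolerance only to absorb floating-point
  noise.
* Baseline correction of an all-zero spectrum is a fixed point; the
  Savitzky–Golay window must be odd, larger than the polynomial order
  and no larger than the grid.
* Percentages in assignment/overlap reports round to the nearest
  integer, matching the worked-example arithmetic they are tested
  against.
* CSV round-trips print doubles with 17 significant digits, so written
  and re-read sets are bit-identical.

# Problem sizes

The package's reference analyses (tests and the acceptance script) run
the full study-shaped preset — 1543 spectra x 1024 bins, an 8-point
hyperparameter grid under 5x3 patient-grouped CV, a WSS scan to K = 50
with 10 restarts, and UMAP on ~1300 spectra — in roughly ten minutes on
a single CPU; unit tests use 64–1024-bin fixtures sized to finish in
seconds. These sizes were chosen to mirror the cohort scale the method
targets while remaining desk-reproducible.

# Known limitations

* The re-implemented baseline is functionally, not bit-exactly,
  equivalent to on-instrument preprocessing; absolute WSS values and
  thresholds are therefore not transferable to instrument-corrected
  data without re-standardization.
* The majority-criterion constants (7 / 0.9 / 3 / size-10 cutoff) are an
  operationalization of a verbal rule; on data without rare subgroups
  the elbow fallback decides, and K should then be read as indicative.
* Probability calibration of the forest is out of scope: the threshold
  transfers a *ranking* cut, not a calibrated probability.
* Multi-class tumor-entity classification, band-to-biomolecule
  assignment and instrument control are out of scope.
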