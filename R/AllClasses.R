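#' @import methods
#' @importFrom stats sd mad runmed rnorm runif predict kmeans hclust cutree dist quantile setNames
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

TISSUE_CLASSES <- c("necrosis", "vital", "heterogeneous",
                    "control_gray", "control_white", "unknown")
KNOWN_TAGS <- c("infiltration_zone", "hemorrhage")

#' Wavenumber grid of a Raman acquisition
#'
#' Describes the shared Raman-shift axis of a set of spectra: `n_bins`
#' equally spaced bin centers between `start` and `end` (cm^-1).
#'
#' @slot start numeric(1), first bin center in cm^-1.
#' @slot end numeric(1), last bin center in cm^-1.
#' @slot n_bins integer(1), number of frequency bins (>= 16).
#'
#' @seealso [wavenumberGrid()], [binCenters()]
#' @export
setClass("WavenumberGrid",
  representation(start = "numeric", end = "numeric", n_bins = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@start) != 1L || length(object@end) != 1L)
      msg <- c(msg, "'start' and 'end' must be scalars")
    else if (!is.finite(object@start) || !is.finite(object@end) ||
             object@start >= object@end)
      msg <- c(msg, "'start' must be finite and < 'end'")
    if (length(object@n_bins) != 1L || is.na(object@n_bins) || object@n_bins < 16L)
      msg <- c(msg, "'n_bins' must be a single integer >= 16")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a wavenumber grid
#'
#' @param start,end range of the Raman-shift axis in cm^-1 (`start < end`).
#' @param n_bins number of equally spaced frequency bins (>= 16). The default
#'   1024-bin grid over the 400--1800 cm^-1 fingerprint region matches a
#'   typical 1024-pixel CCD detector and keeps even narrow Raman bands
#'   several bins wide.
#' @return A [WavenumberGrid-class] object.
#' @examples
#' g <- wavenumberGrid(400, 1800, 1024)
#' head(binCenters(g))
#' @export
wavenumberGrid <- function(start = 400, end = 1800, n_bins = 1024L) {
  new("WavenumberGrid", start = as.numeric(start), end = as.numeric(end),
      n_bins = as.integer(n_bins))
}

#' @describeIn WavenumberGrid-class bin centers in cm^-1 (strictly increasing).
#' @param object,x a `WavenumberGrid`.
#' @export
binCenters <- function(x) {
  stopifnot(is(x, "WavenumberGrid"))
  seq(x@start, x@end, length.out = x@n_bins)
}

setMethod("show", "WavenumberGrid", function(object) {
  cat(sprintf("WavenumberGrid: %g..%g cm^-1, %d bins (%.2f cm^-1/bin)\n",
              object@start, object@end, object@n_bins,
              (object@end - object@start) / (object@n_bins - 1L)))
})

#' SpectraSet: a collection of Raman spectra on one wavenumber grid
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with one assay,
#' `"intensity"` (frequency bins x spectra). `rowData` holds the wavenumber of
#' every bin; `colData` carries the per-spectrum metadata (patient, specimen,
#' histological class label, tags, acquisition parameters).  `metadata()`
#' stores the [WavenumberGrid-class], a provenance log of applied processing
#' steps and, after [standardizeSpectra()], the stored standardization
#' statistics.
#'
#' Required `colData` columns: `patient_id`, `specimen_id`, `class_label`
#' (one of necrosis, vital, heterogeneous, control_gray, control_white,
#' unknown), `tags` (`;`-separated, possibly empty), `acquisition_time_s`
#' (> 0) and `n_acquisitions` (1..30). Column names are the spectrum ids and
#' must be unique.
#'
#' @seealso [newSpectraSet()], [intensities()], [spectrumMeta()],
#'   [provenance()]
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
      return("assay 'intensity' missing")
    m <- SummarizedExperiment::assay(object, "intensity")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
      msg <- c(msg, "spectrum ids (colnames) must be present and unique")
    if (ncol(object) > 0L && !all(is.finite(m)))
      msg <- c(msg, "all intensities must be finite")
    g <- S4Vectors::metadata(object)$grid
    if (!is(g, "WavenumberGrid"))
      msg <- c(msg, "metadata()$grid must be a WavenumberGrid")
    else if (nrow(object) != g@n_bins)
      msg <- c(msg, "number of rows must equal grid n_bins")
    cd <- SummarizedExperiment::colData(object)
    need <- c("patient_id", "specimen_id", "class_label", "tags",
              "acquisition_time_s", "n_acquisitions")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
      msg <- c(msg, paste0("missing colData columns: ",
                           paste(miss, collapse = ", ")))
    else if (ncol(object) > 0L) {
      if (!all(cd$class_label %in% TISSUE_CLASSES))
        msg <- c(msg, "invalid class_label value(s)")
      if (!all(cd$acquisition_time_s > 0))
        msg <- c(msg, "acquisition_time_s must be > 0")
      if (!all(cd$n_acquisitions >= 1L & cd$n_acquisitions <= 30L))
        msg <- c(msg, "n_acquisitions must be in 1..30")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Construct a SpectraSet
#'
#' @param intensity numeric matrix, frequency bins x spectra.
#' @param meta `data.frame` or `DataFrame` of per-spectrum metadata, one row
#'   per column of `intensity`; must contain `spectrum_id`, `patient_id`,
#'   `specimen_id`, `class_label`, `acquisition_time_s`, `n_acquisitions`
#'   and optionally `tags`.
#' @param grid the shared [WavenumberGrid-class].
#' @param provenance character vector of already-applied processing steps.
#' @return A [SpectraSet-class].
#' @export
newSpectraSet <- function(intensity, meta, grid, provenance = character()) {
  meta <- as.data.frame(meta)
  stopifnot(is.matrix(intensity), nrow(meta) == ncol(intensity),
            "spectrum_id" %in% colnames(meta))
  if (is.null(meta$tags)) meta$tags <- ""
  meta$tags[is.na(meta$tags)] <- ""
  colnames(intensity) <- as.character(meta$spectrum_id)
  rownames(intensity) <- format(binCenters(grid), trim = TRUE)
  cd <- S4Vectors::DataFrame(meta[setdiff(colnames(meta), "spectrum_id")],
                             row.names = meta$spectrum_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = S4Vectors::DataFrame(wavenumber = binCenters(grid)),
    colData = cd)
  S4Vectors::metadata(se)$grid <- grid
  S4Vectors::metadata(se)$provenance <- provenance
  new("SpectraSet", se)
}

#' @describeIn SpectraSet-class the intensity matrix (bins x spectra).
#' @param x a `SpectraSet`.
#' @export
intensities <- function(x) {
  stopifnot(is(x, "SpectraSet"))
  SummarizedExperiment::assay(x, "intensity")
}

#' @describeIn SpectraSet-class wavenumber of each frequency bin (cm^-1).
#' @export
wavenumbers <- function(x) {
  stopifnot(is(x, "SpectraSet"))
  SummarizedExperiment::rowData(x)$wavenumber
}

#' @describeIn SpectraSet-class per-spectrum metadata as a `data.frame`
#'   (with a `spectrum_id` column).
#' @export
spectrumMeta <- function(x) {
  stopifnot(is(x, "SpectraSet"))
  d <- as.data.frame(SummarizedExperiment::colData(x))
  cbind(spectrum_id = colnames(x), d, stringsAsFactors = FALSE)
}

#' @describeIn SpectraSet-class the grid the spectra share.
#' @export
spectraGrid <- function(x) {
  stopifnot(is(x, "SpectraSet"))
  S4Vectors::metadata(x)$grid
}

#' @describeIn SpectraSet-class log of processing steps applied so far.
#' @export
provenance <- function(x) {
  stopifnot(is(x, "SpectraSet"))
  S4Vectors::metadata(x)$provenance
}

addProvenance <- function(x, step) {
  S4Vectors::metadata(x)$provenance <- c(S4Vectors::metadata(x)$provenance, step)
  x
}

#' @describeIn SpectraSet-class logical: does each spectrum carry `tag`?
#' @param tag tag name, e.g. `"infiltration_zone"`.
#' @export
hasTag <- function(x, tag) {
  stopifnot(is(x, "SpectraSet"))
  vapply(strsplit(SummarizedExperiment::colData(x)$tags, ";", fixed = TRUE),
         function(tt) tag %in% tt, logical(1L))
}

setMethod("show", "SpectraSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("SpectraSet: %d spectra x %d bins, %d patient(s)\n",
              ncol(object), nrow(object),
              length(unique(cd$patient_id))))
  if (ncol(object)) {
    tb <- table(cd$class_label)
    cat("  classes:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  show(S4Vectors::metadata(object)$grid)
  pv <- provenance(object)
  if (length(pv)) cat("  provenance:", paste(pv, collapse = " -> "), "\n")
})

#' Patient-wise train/validation split plan
#'
#' Produced by [splitPatientwise()]: patients (never individual spectra) are
#' assigned to exactly one of the two splits, and within each patient the
#' spectra of each class are subsampled to at most `per_patient_cap`.
#'
#' @slot train_patients,validation_patients character vectors of patient ids
#'   (disjoint).
#' @slot per_patient_cap integer cap on spectra per patient and class.
#' @slot train_ids,validation_ids spectrum ids retained in each split.
#' @slot counts `data.frame` of spectra per split and class.
#' @export
setClass("SplitPlan",
  representation(train_patients = "character",
                 validation_patients = "character",
                 per_patient_cap = "integer",
                 train_ids = "character",
                 validation_ids = "character",
                 counts = "data.frame"),
  validity = function(object) {
    msg <- NULL
    if (length(intersect(object@train_patients, object@validation_patients)))
      msg <- c(msg, "train and validation patient sets must be disjoint")
    if (length(intersect(object@train_ids, object@validation_ids)))
      msg <- c(msg, "train and validation spectra must be disjoint")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf(
    "SplitPlan: %d train / %d validation patients, cap %d spectra/patient/class\n",
    length(object@train_patients), length(object@validation_patients),
    object@per_patient_cap))
  print(object@counts)
})

#' Fitted necrosis/vital random-forest classifier
#'
#' Produced by [tuneAndFit()]. The score emitted by the model is always the
#' probability that a spectrum is spectroscopically *necrotic*; spectra with
#' score >= `threshold` are labeled necrotic. The decision threshold is
#' derived from the out-of-fold scores of the internal cross-validation only,
#' never from external validation data.
#'
#' @slot forest the fitted [ranger::ranger] probability forest.
#' @slot threshold f1-optimal decision threshold on the necrosis-probability
#'   axis.
#' @slot cv_summary per-fold internal CV metrics for the selected
#'   hyperparameters.
#' @slot tuning grid-point performance table used for hyperparameter
#'   selection.
#' @slot hyperparameters the selected hyperparameters.
#' @slot oof out-of-fold score table (spectrum id, repeat, score, label).
#' @slot train_patients patient ids seen during training (leakage guard).
#' @slot wavenumber_fingerprint the training grid's wavenumbers; scoring a
#'   set on a different grid is refused.
#' @slot standardization the standardization statistics the training set was
#'   processed with (see [standardizeSpectra()]).
#' @export
setClass("ClassifierModel",
  representation(forest = "ANY", threshold = "numeric",
                 cv_summary = "data.frame", tuning = "data.frame",
                 hyperparameters = "list", oof = "data.frame",
                 train_patients = "character",
                 wavenumber_fingerprint = "numeric",
                 standardization = "list"),
  validity = function(object) {
    if (length(object@threshold) != 1L || object@threshold < 0 ||
        object@threshold > 1)
      "threshold must be a single probability in [0, 1]" else TRUE
  })

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf(
    "ClassifierModel: random forest (%d trees), decision threshold %.3f\n",
    object@forest$num.trees, object@threshold))
  cat(sprintf("  trained on %d patients; internal CV mean f1 %.3f, AUROC %.3f\n",
              length(object@train_patients),
              mean(object@cv_summary$f1, na.rm = TRUE),
              mean(object@cv_summary$auroc, na.rm = TRUE)))
})

#' Within-cluster sum-of-squares curve over K
#'
#' Produced by [wssCurve()]: for each K in 1..kmax the inertia (within-cluster
#' sum of squared Euclidean errors) of the best of `n_init` k-means fits, plus
#' the cluster sizes at each K.
#'
#' @slot wss numeric vector, WSS per K (named "1".."kmax").
#' @slot sizes list of integer cluster-size vectors per K.
#' @slot n_init,seed number of k-means++ restarts per K and RNG seed.
#' @slot total_ss total sum of squares of the data (equals `wss[1]`).
#' @export
setClass("WSSCurve",
  representation(wss = "numeric", sizes = "list", n_init = "integer",
                 seed = "integer", total_ss = "numeric"),
  validity = function(object) {
    if (length(object@wss) != length(object@sizes))
      "wss and sizes must cover the same K range" else TRUE
  })

setMethod("show", "WSSCurve", function(object) {
  cat(sprintf("WSSCurve: K = 1..%d, n_init = %d, WSS(1) = %.4g, WSS(kmax) = %.4g\n",
              length(object@wss), object@n_init, object@wss[1],
              object@wss[length(object@wss)]))
})

#' Fitted k-means cluster model of the spectral-vital subset
#'
#' Produced by [fitClusters()]. Clustering operates in the standardized
#' spectral feature space (never in the 2-D embedding). Cluster ids are
#' renumbered by decreasing size, so cluster 1 is always the largest.
#'
#' @slot K number of clusters.
#' @slot centroids K x n_bins matrix of cluster centroids.
#' @slot labels named integer vector, cluster id per spectrum id.
#' @slot inertia total within-cluster sum of squared errors.
#' @slot n_init,seed restarts and RNG seed used.
#' @slot wavenumbers grid fingerprint for external assignment checks.
#' @export
setClass("ClusterModel",
  representation(K = "integer", centroids = "matrix", labels = "integer",
                 inertia = "numeric", n_init = "integer", seed = "integer",
                 wavenumbers = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@centroids) != object@K)
      msg <- c(msg, "centroids must have K rows")
    if (!all(object@labels >= 1L & object@labels <= object@K))
      msg <- c(msg, "labels must be in 1..K")
    if (is.null(names(object@labels)))
      msg <- c(msg, "labels must be named by spectrum id")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "ClusterModel", function(object) {
  sz <- sort(table(factor(object@labels, levels = seq_len(object@K))),
             decreasing = TRUE)
  cat(sprintf("ClusterModel: K = %d on %d spectra, inertia %.4g\n",
              object@K, length(object@labels), object@inertia))
  cat("  sizes:", paste(as.integer(sz), collapse = ", "), "\n")
})
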