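## warn when a processing step is applied twice; the canonical order is
## remove_cosmic_rays -> baseline_correct -> standardize
warnIfReprocessed <- function(set, step) {
  if (step %in% provenance(set))
    warning("step '", step, "' already recorded in provenance; ",
            "re-running on processed data", call. = FALSE)
}

#' Remove cosmic-ray spikes and hot pixels
#'
#' Single-bin artifacts are detected per spectrum as bins whose residual
#' against a running median (window 5 bins) exceeds `z_threshold` times the
#' robust residual sd (MAD); flagged bins are replaced by the running-median
#' value. Saturated hot pixels are caught by the same rule.
#'
#' @param set a [SpectraSet-class] of raw spectra.
#' @param z_threshold robust z-score cutoff (> 0); 8 keeps the false-positive
#'   rate on spike-free Gaussian noise essentially at zero.
#' @return The corrected `SpectraSet`; `metadata()$cosmic_ray_report` holds
#'   the number of corrected bins per spectrum.
#' @export
removeCosmicRays <- function(set, z_threshold = 8) {
  stopifnot(is(set, "SpectraSet"), z_threshold > 0)
  if (nrow(set) < 5L)
    stop("configuration error: running-median window (5) larger than grid")
  warnIfReprocessed(set, "remove_cosmic_rays")
  x <- intensities(set)
  corrected <- integer(ncol(x))
  for (j in seq_len(ncol(x))) {
    med <- runmed(x[, j], 5L, endrule = "median")
    resid <- x[, j] - med
    ## robust noise floor from first differences: immune to the smooth
    ## background slope, on which running-median residuals degenerate
    rsd <- mad(diff(x[, j])) / sqrt(2)
    if (rsd == 0) rsd <- .Machine$double.eps
    bad <- abs(resid) > z_threshold * rsd
    if (any(bad)) {
      x[bad, j] <- med[bad]
      corrected[j] <- sum(bad)
    }
  }
  out <- set
  SummarizedExperiment::assay(out, "intensity") <- x
  S4Vectors::metadata(out)$cosmic_ray_report <-
    list(z_threshold = z_threshold, total_corrected = sum(corrected),
         per_spectrum = setNames(corrected, colnames(set)))
  validObject(out)
  addProvenance(out, "remove_cosmic_rays")
}

## iterative Savitzky-Golay baseline of one spectrum: smooth, clamp the
## working curve to the smooth from above (suppressing peaks), re-smooth
sgBaseline <- function(y, window, polyorder, iterations = 10L) {
  b <- y
  s <- y
  for (i in seq_len(iterations)) {
    s <- signal::sgolayfilt(b, p = polyorder, n = window)
    b <- pmin(b, s)
  }
  s
}

#' Baseline and fluorescence removal
#'
#' Estimates a smooth baseline per spectrum by iterative Savitzky-Golay
#' smoothing with peak suppression (points above the current smooth curve
#' are replaced by the curve, then re-smoothed; 10 fixed iterations) and
#' subtracts it. Broad fluorescence background is removed while narrow Raman
#' peaks survive. Small negative residuals are retained -- the later
#' standardization makes the sign irrelevant.
#'
#' @param set a [SpectraSet-class].
#' @param window odd Savitzky-Golay window length in bins; must be much wider
#'   than the Raman peaks but narrow enough to track the background.
#' @param polyorder polynomial order (< window).
#' @return The baseline-corrected `SpectraSet`.
#' @export
baselineCorrect <- function(set, window = 101L, polyorder = 3L) {
  stopifnot(is(set, "SpectraSet"))
  window <- as.integer(window)
  if (window %% 2L == 0L || polyorder >= window || window > nrow(set))
    stop("configuration error: need odd 'window' with polyorder < window <= n_bins")
  warnIfReprocessed(set, "baseline_correct")
  x <- intensities(set)
  for (j in seq_len(ncol(x)))
    x[, j] <- x[, j] - sgBaseline(x[, j], window, polyorder)
  out <- set
  SummarizedExperiment::assay(out, "intensity") <- x
  validObject(out)
  addProvenance(out, "baseline_correct")
}

#' Two-stage standardization (SNV, then per-bin)
#'
#' Stage 1 applies the standard normal variate: every spectrum is centered
#' and scaled to unit sd across its bins, removing multiplicative gain and
#' additive offset differences between acquisitions. Stage 2 centers and
#' scales every frequency bin to unit sd across spectra. The stage-2 bin
#' means and sds are stored in `metadata()$standardization` so that external
#' spectra (e.g. healthy controls) can later be standardized with the *same*
#' statistics via [applyStandardization()].
#'
#' Spectra with zero variance cannot be SNV-scaled; they are dropped with a
#' warning.
#'
#' @param set a [SpectraSet-class] with at least two spectra.
#' @return The standardized `SpectraSet` (every bin has mean 0, sd 1 across
#'   spectra).
#' @export
standardizeSpectra <- function(set) {
  stopifnot(is(set, "SpectraSet"), ncol(set) >= 2L)
  warnIfReprocessed(set, "standardize")
  x <- intensities(set)
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    warning("excluding ", sum(sds == 0),
            " constant spectrum(-a) that cannot be standardized: ",
            paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
    set <- set[, sds > 0]
    x <- intensities(set)
  }
  x <- scale(x)                      # stage 1: SNV per spectrum (column)
  bm <- rowMeans(x)
  bs <- apply(x, 1L, sd)
  bs[bs == 0] <- 1
  x <- (x - bm) / bs                 # stage 2: per frequency bin
  out <- set
  SummarizedExperiment::assay(out, "intensity") <-
    matrix(x, nrow(set), dimnames = dimnames(intensities(set)))
  S4Vectors::metadata(out)$standardization <-
    list(bin_means = unname(bm), bin_sds = unname(bs),
         wavenumbers = as.numeric(wavenumbers(set)))
  validObject(out)
  addProvenance(out, "standardize")
}

#' Standardize spectra with stored statistics
#'
#' Applies stage 1 (SNV) and then the *stored* stage-2 bin means/sds of a
#' previously standardized training set. Required whenever external spectra
#' must live in the training feature space: classifier scoring and
#' nearest-centroid assignment of healthy controls.
#'
#' @param set a [SpectraSet-class] (raw or baseline-corrected, not yet
#'   standardized).
#' @param stats the `metadata()$standardization` list of the training set.
#' @return The standardized `SpectraSet`.
#' @export
applyStandardization <- function(set, stats) {
  stopifnot(is(set, "SpectraSet"),
            is.list(stats), !is.null(stats$bin_means), !is.null(stats$bin_sds))
  if (length(stats$bin_means) != nrow(set) ||
      !isTRUE(all.equal(stats$wavenumbers, wavenumbers(set))))
    stop("grid mismatch: stored standardization statistics were computed on ",
         "a different wavenumber grid")
  x <- intensities(set)
  sds <- apply(x, 2L, sd)
  if (any(sds == 0))
    stop("constant spectrum(-a) cannot be standardized: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  x <- scale(x)
  x <- (x - stats$bin_means) / stats$bin_sds
  out <- set
  SummarizedExperiment::assay(out, "intensity") <-
    matrix(x, nrow(set), dimnames = dimnames(intensities(set)))
  S4Vectors::metadata(out)$standardization <- stats
  validObject(out)
  addProvenance(out, "standardize(stored)")
}

#' Dendrogram QC scan for strong outliers
#'
#' Ward-linkage agglomerative clustering on Euclidean distances between
#' standardized spectra; the top three split levels of the dendrogram are
#' summarized. A spectrum is flagged as a strong outlier if, at any of the
#' top three levels, it sits in a branch smaller than `max(2, 0.5%)` of the
#' data -- i.e. an isolated twig directly under the root.
#'
#' @param set a standardized [SpectraSet-class] with n >= 4.
#' @param min_branch_fraction branch-size fraction below which a top-level
#'   branch counts as outlying (default 0.005).
#' @return A `qc_report` list: `levels` (per level: cut height and branch
#'   sizes), `flagged` spectrum ids and the `verdict` ("strong outliers
#'   present").
#' @export
qcDendrogram <- function(set, min_branch_fraction = 0.005) {
  stopifnot(is(set, "SpectraSet"))
  n <- ncol(set)
  if (n < 4L) stop("input error: QC dendrogram needs at least 4 spectra")
  if (!"standardize" %in% provenance(set) &&
      !"standardize(stored)" %in% provenance(set))
    warning("QC scan expects standardized spectra", call. = FALSE)
  h <- hclust(dist(t(intensities(set))), method = "ward.D2")
  tol <- max(h$height) * 1e-10 + 1e-12
  hts <- sort(unique(h$height[h$height > tol]), decreasing = TRUE)
  hts <- utils::head(hts, 3L)
  min_size <- max(2L, ceiling(min_branch_fraction * n))
  flagged <- character()
  levels <- list()
  for (i in seq_along(hts)) {
    grp <- cutree(h, h = hts[i] - tol)
    sz <- table(grp)
    levels[[i]] <- list(merge_height = hts[i],
                        branch_sizes = sort(as.integer(sz),
                                            decreasing = TRUE))
    small <- names(sz)[sz < min_size]
    flagged <- union(flagged, names(grp)[grp %in% as.integer(small)])
  }
  structure(list(n = n, levels = levels,
                 merge_heights = if (length(hts)) hts else 0,
                 min_branch_size = min_size,
                 flagged = flagged,
                 verdict = length(flagged) > 0L),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Dendrogram QC on %d spectra: strong outliers %s\n", x$n,
              if (x$verdict) "PRESENT" else "absent"))
  for (i in seq_along(x$levels))
    cat(sprintf("  level %d (merge height %.3g): branch sizes %s\n", i,
                x$levels[[i]]$merge_height,
                paste(x$levels[[i]]$branch_sizes, collapse = ", ")))
  if (length(x$flagged))
    cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
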