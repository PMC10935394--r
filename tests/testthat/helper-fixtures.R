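# shared fixtures: everything is generated in code at test time

tinyGrid <- function(n_bins = 64L) wavenumberGrid(400, 1800, n_bins)

# broad single-peak profile: smooth template, no narrow structure
broadProfile <- function(amp = 100)
  tissueProfile("broad", list(peakSpec(1100, 500, amp)))

# two well-separated classes (necrosis vs one vital subtype)
twoClassCohort <- function(n_pat = 4L, n_spec = 10L, n_bins = 64L,
                           seed = 5L, noise = 0.6, gain_sd = 0.15,
                           shift_sd = 1, ...) {
  pr <- defaultTissueProfiles()[c("necrosis", "vital_1")]
  cfg <- cohortConfig(tinyGrid(n_bins), pr,
                      n_patients_per_class = c(necrosis = n_pat,
                                               vital = n_pat),
                      spectra_per_patient = n_spec,
                      class_profiles = c(necrosis = "necrosis",
                                         vital = "vital_1"),
                      patient_gain_sd = gain_sd,
                      patient_shift_sd = shift_sd,
                      noise_sd_base = noise, seed = seed, ...)
  generateCohort(cfg)
}

preprocessAll <- function(set, window = 41L)
  standardizeSpectra(baselineCorrect(removeCosmicRays(set), window, 3L))

# SpectraSet straight from an intensity matrix (bins x spectra)
matrixSet <- function(x, grid = NULL, patient_id = NULL,
                      class_label = "vital", tags = "",
                      provenance = character()) {
  if (is.null(grid)) grid <- wavenumberGrid(400, 1800, nrow(x))
  n <- ncol(x)
  if (is.null(patient_id)) patient_id <- rep("P01", n)
  meta <- data.frame(spectrum_id = sprintf("S%03d", seq_len(n)),
                     patient_id = patient_id,
                     specimen_id = paste0(patient_id, "-S01"),
                     class_label = rep_len(class_label, n),
                     tags = rep_len(tags, n),
                     acquisition_time_s = 1, n_acquisitions = 1L,
                     stringsAsFactors = FALSE)
  newSpectraSet(x, meta, grid, provenance = provenance)
}

# planted Gaussian blobs in spectral feature space, one patient per blob
blobSet <- function(centers, n_per, sd = 0.2, seed = 1L) {
  d <- ncol(centers)
  k <- nrow(centers)
  n_per <- rep_len(n_per, k)
  withr::with_seed(seed, {
    x <- do.call(cbind, lapply(seq_len(k), function(i)
      matrix(rnorm(d * n_per[i], mean = rep(centers[i, ], each = 1),
                   sd = sd), nrow = d)))
  })
  set <- matrixSet(x, patient_id = rep(sprintf("P%02d", seq_len(k)), n_per),
                   provenance = "standardize")
  attr(set, "blob") <- rep(seq_len(k), n_per)
  set
}

# hand-built cluster model with given centroids (K x n_bins)
handClusterModel <- function(centroids, labels = NULL) {
  K <- nrow(centroids)
  if (is.null(labels))
    labels <- setNames(rep(1L, K), sprintf("T%03d", seq_len(K)))
  rownames(centroids) <- as.character(seq_len(K))
  grid <- wavenumberGrid(400, 1800, ncol(centroids))
  new("ClusterModel", K = as.integer(K), centroids = centroids,
      labels = labels, inertia = 0, n_init = 1L, seed = 1L,
      wavenumbers = binCenters(grid))
}

# f1 of the necrosis class for a hard labeling
f1Necrosis <- function(pred_pos, labels) {
  pos <- labels == "necrosis"
  tp <- sum(pos & pred_pos); fp <- sum(!pos & pred_pos)
  fn <- sum(pos & !pred_pos)
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}
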