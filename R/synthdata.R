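#' Gaussian peak of a tissue-class spectral profile
#'
#' @param center peak position in cm^-1.
#' @param width Gaussian sigma in cm^-1 (> 0).
#' @param amplitude peak height in arbitrary intensity units (>= 0).
#' @return A `peak_spec` list.
#' @export
peakSpec <- function(center, width, amplitude) {
  stopifnot(is.finite(center), width > 0, amplitude >= 0)
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "peak_spec")
}

#' Spectral profile of a tissue class
#'
#' The noiseless molecular fingerprint a tissue class emits: a sum of
#' Gaussian peaks on top of a single decaying-exponential fluorescence
#' background. Gaussian line shapes suffice here because no downstream step
#' exploits the line shape, and a single exponential is a smooth, broad
#' background that the baseline-correction stage is expected to remove.
#'
#' @param name profile name (free text, e.g. `"necrosis"`, `"vital_1"`).
#' @param peaks list of [peakSpec()] entries (at least one).
#' @param fluorescence_amplitude intensity of the fluorescence background at
#'   the start of the grid (>= 0).
#' @param fluorescence_decay decay constant of the background in 1/cm^-1.
#' @return A `tissue_profile` list.
#' @export
tissueProfile <- function(name, peaks, fluorescence_amplitude = 0,
                          fluorescence_decay = 0.0015) {
  stopifnot(is.character(name), length(peaks) >= 1L,
            all(vapply(peaks, inherits, logical(1L), "peak_spec")),
            fluorescence_amplitude >= 0, fluorescence_decay >= 0)
  structure(list(name = name, peaks = peaks,
                 fluorescence_amplitude = fluorescence_amplitude,
                 fluorescence_decay = fluorescence_decay),
            class = "tissue_profile")
}

## noiseless template of a profile on a grid, with a per-patient global shift
profileTemplate <- function(profile, grid, shift = 0) {
  nu <- binCenters(grid)
  y <- profile$fluorescence_amplitude *
    exp(-profile$fluorescence_decay * (nu - grid@start))
  for (p in profile$peaks) {
    ctr <- p$center + shift
    if (ctr < grid@start || ctr > grid@end)
      stop("configuration error: peak at ", p$center,
           " cm^-1 falls outside the grid after shift")
    y <- y + p$amplitude * exp(-0.5 * ((nu - ctr) / p$width)^2)
  }
  y
}

#' Simulate a single Raman spectrum
#'
#' Draws one synthetic spectrum: the profile template (peaks shifted by the
#' patient's wavenumber offset, plus fluorescence background) is scaled by the
#' patient gain, and Gaussian detector noise with standard deviation
#' `noise_sd_base / sqrt(acquisition_time)` is added -- longer exposures
#' average the shot noise down. With the configured probabilities a single-bin
#' cosmic-ray spike (amplitude at least 10x the strongest peak) and/or a
#' saturated hot pixel are injected. Intensities are clipped at zero.
#'
#' Uses R's global RNG; wrap in [withr::with_seed()] (or call `set.seed()`)
#' for reproducibility.
#'
#' @param profile a [tissueProfile()].
#' @param grid the [WavenumberGrid-class].
#' @param patient_gain multiplicative patient gain (> 0).
#' @param patient_shift per-patient wavenumber offset in cm^-1.
#' @param acquisition_time exposure time in seconds (> 0).
#' @param noise_sd_base detector noise sd at 1 s exposure.
#' @param cosmic_ray_rate,hot_pixel_rate per-spectrum artifact probabilities
#'   in `[0, 1]`.
#' @param hot_pixel_bin index of the detector's hot pixel (fixed per
#'   instrument); drawn uniformly if `NULL` and needed.
#' @param saturation intensity value of a saturated pixel.
#' @return list with `intensities` (numeric vector over the grid), the
#'   noiseless `template`, and the injected artifact bins (`cosmic_bin`,
#'   `hot_bin`; `NA` if none).
#' @examples
#' g <- wavenumberGrid(400, 1800, 1024)
#' pr <- tissueProfile("demo", list(peakSpec(1000, 10, 5)))
#' s <- generateSpectrum(pr, g, acquisition_time = 1)
#' max(s$intensities)  # ~5 at the bin nearest 1000 cm^-1
#' @export
generateSpectrum <- function(profile, grid, patient_gain = 1,
                             patient_shift = 0, acquisition_time = 1,
                             noise_sd_base = 0, cosmic_ray_rate = 0,
                             hot_pixel_rate = 0, hot_pixel_bin = NULL,
                             saturation = 6.5e4) {
  stopifnot(is(grid, "WavenumberGrid"), patient_gain > 0,
            acquisition_time > 0, noise_sd_base >= 0,
            cosmic_ray_rate >= 0, cosmic_ray_rate <= 1,
            hot_pixel_rate >= 0, hot_pixel_rate <= 1)
  template <- patient_gain * profileTemplate(profile, grid, patient_shift)
  noise_sd <- noise_sd_base / sqrt(acquisition_time)
  y <- template
  if (noise_sd > 0) y <- y + rnorm(grid@n_bins, 0, noise_sd)
  cosmic_bin <- NA_integer_
  if (cosmic_ray_rate > 0 && runif(1L) < cosmic_ray_rate) {
    cosmic_bin <- sample.int(grid@n_bins, 1L)
    peak_max <- max(vapply(profile$peaks, `[[`, numeric(1L), "amplitude"), 1)
    y[cosmic_bin] <- y[cosmic_bin] + runif(1L, 10, 20) * peak_max
  }
  y <- pmax(y, 0)
  hot_bin <- NA_integer_
  if (hot_pixel_rate > 0 && runif(1L) < hot_pixel_rate) {
    hot_bin <- if (is.null(hot_pixel_bin)) sample.int(grid@n_bins, 1L)
               else as.integer(hot_pixel_bin)
    y[hot_bin] <- saturation
  }
  list(intensities = y, template = template,
       cosmic_bin = cosmic_bin, hot_bin = hot_bin)
}

#' Configuration of a synthetic multi-patient cohort
#'
#' Either give the uniform design (`n_patients_per_class` x
#' `spectra_per_patient`, one profile per class via `class_profiles`) or an
#' explicit `allocation` table with one row per (patient, class, profile)
#' block -- the latter is how the study-shaped preset encodes its uneven
#' class sizes.
#'
#' @param grid shared [WavenumberGrid-class].
#' @param profiles named list of [tissueProfile()] objects.
#' @param n_patients_per_class named integer vector (names are class labels).
#' @param spectra_per_patient spectra per patient in the uniform design.
#' @param class_profiles named character vector mapping class label to
#'   profile name; defaults to identical names.
#' @param allocation `data.frame` with columns `patient_id`, `class_label`,
#'   `profile`, `n_spectra` and optionally `tags` (`;`-separated).
#' @param patient_gain_sd sd of the per-patient log-normal gain (a
#'   multiplicative batch effect drawn once per patient).
#' @param patient_shift_sd sd (cm^-1) of the per-patient wavenumber offset.
#' @param noise_sd_base detector noise sd at 1 s exposure.
#' @param acquisition_time_range exposure range in seconds; spectra draw
#'   uniformly from it (instrument regime 0.7--10 s).
#' @param cosmic_ray_rate,hot_pixel_rate per-spectrum artifact probabilities.
#' @param seed integer RNG seed; the cohort is fully reproducible from it.
#' @return A `cohort_config` list (validated).
#' @export
cohortConfig <- function(grid, profiles, n_patients_per_class = NULL,
                         spectra_per_patient = NULL, class_profiles = NULL,
                         allocation = NULL, patient_gain_sd = 0.15,
                         patient_shift_sd = 1, noise_sd_base = 0.6,
                         acquisition_time_range = c(0.7, 10),
                         cosmic_ray_rate = 0, hot_pixel_rate = 0,
                         seed = 1L) {
  stopifnot(is(grid, "WavenumberGrid"), length(profiles) >= 1L,
            !is.null(names(profiles)),
            all(vapply(profiles, inherits, logical(1L), "tissue_profile")),
            patient_gain_sd >= 0, patient_shift_sd >= 0, noise_sd_base >= 0,
            length(acquisition_time_range) == 2L,
            acquisition_time_range[1] > 0,
            acquisition_time_range[1] <= acquisition_time_range[2],
            cosmic_ray_rate >= 0, cosmic_ray_rate <= 1,
            hot_pixel_rate >= 0, hot_pixel_rate <= 1)
  if (is.null(allocation)) {
    if (is.null(n_patients_per_class) || is.null(spectra_per_patient))
      stop("configuration error: give either 'allocation' or both ",
           "'n_patients_per_class' and 'spectra_per_patient'")
    if (any(n_patients_per_class < 1L))
      stop("configuration error: every class needs at least one patient")
    if (is.null(class_profiles))
      class_profiles <- setNames(names(n_patients_per_class),
                                 names(n_patients_per_class))
    rows <- list()
    pid <- 0L
    for (cl in names(n_patients_per_class)) {
      prof <- class_profiles[[cl]]
      if (!prof %in% names(profiles))
        stop("configuration error: no profile named '", prof, "'")
      for (i in seq_len(n_patients_per_class[[cl]])) {
        pid <- pid + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = sprintf("P%02d", pid), class_label = cl,
          profile = prof, n_spectra = spectra_per_patient, tags = "",
          stringsAsFactors = FALSE)
      }
    }
    allocation <- do.call(rbind, rows)
  }
  stopifnot(all(c("patient_id", "class_label", "profile", "n_spectra") %in%
                colnames(allocation)))
  if (is.null(allocation$tags)) allocation$tags <- ""
  if (nrow(allocation) == 0L || sum(allocation$n_spectra) == 0L)
    stop("configuration error: cohort must contain at least one spectrum")
  if (!all(allocation$profile %in% names(profiles)))
    stop("configuration error: allocation references unknown profile(s)")
  if (!all(allocation$class_label %in% TISSUE_CLASSES))
    stop("configuration error: invalid class label in allocation")
  structure(list(grid = grid, profiles = profiles, allocation = allocation,
                 patient_gain_sd = patient_gain_sd,
                 patient_shift_sd = patient_shift_sd,
                 noise_sd_base = noise_sd_base,
                 acquisition_time_range = acquisition_time_range,
                 cosmic_ray_rate = cosmic_ray_rate,
                 hot_pixel_rate = hot_pixel_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic multi-patient Raman cohort
#'
#' For every patient one multiplicative gain (log-normal with sd
#' `patient_gain_sd` on the log scale) and one global wavenumber shift
#' (normal, sd `patient_shift_sd`) are drawn once and applied to all of that
#' patient's spectra; each spectrum then follows the noise and artifact model
#' of [generateSpectrum()]. The hot pixel sits at one fixed detector bin for
#' the whole cohort. Fully reproducible from `config$seed`.
#'
#' @param config a [cohortConfig()].
#' @return list with `spectra` (a [SpectraSet-class] of raw spectra),
#'   `truth` (`data.frame` of per-spectrum latent draws: generating profile,
#'   patient gain/shift, injected artifact bins) and `patients` (the
#'   per-patient latent draws).
#' @examples
#' g <- wavenumberGrid(400, 1800, 64)
#' pr <- list(a = tissueProfile("a", list(peakSpec(800, 15, 5))),
#'            b = tissueProfile("b", list(peakSpec(1400, 15, 5))))
#' cfg <- cohortConfig(g, pr,
#'                     n_patients_per_class = c(vital = 2, necrosis = 2),
#'                     spectra_per_patient = 5,
#'                     class_profiles = c(vital = "a", necrosis = "b"),
#'                     seed = 7)
#' coh <- generateCohort(cfg)
#' coh$spectra
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  alloc <- config$allocation
  grid <- config$grid
  withr::with_seed(config$seed, {
    pats <- unique(alloc$patient_id)
    pt <- data.frame(patient_id = pats,
                     gain = exp(rnorm(length(pats), 0, config$patient_gain_sd)),
                     shift = rnorm(length(pats), 0, config$patient_shift_sd),
                     stringsAsFactors = FALSE)
    hot_pixel_bin <- sample.int(grid@n_bins, 1L)
    n_total <- sum(alloc$n_spectra)
    intens <- matrix(0, grid@n_bins, n_total)
    meta <- vector("list", nrow(alloc))
    truth <- vector("list", nrow(alloc))
    col <- 0L
    for (r in seq_len(nrow(alloc))) {
      row <- alloc[r, ]
      p <- pt[pt$patient_id == row$patient_id, ]
      n <- row$n_spectra
      if (n == 0L) next
      ids <- sprintf("%s_%s_%03d", row$patient_id, row$profile,
                     seq_len(n) + sum(alloc$n_spectra[seq_len(r - 1L)][
                       alloc$patient_id[seq_len(r - 1L)] == row$patient_id]))
      acq <- runif(n, config$acquisition_time_range[1],
                   config$acquisition_time_range[2])
      nacq <- sample.int(30L, n, replace = TRUE)
      cb <- hb <- rep(NA_integer_, n)
      for (j in seq_len(n)) {
        s <- generateSpectrum(config$profiles[[row$profile]], grid,
                              patient_gain = p$gain, patient_shift = p$shift,
                              acquisition_time = acq[j],
                              noise_sd_base = config$noise_sd_base,
                              cosmic_ray_rate = config$cosmic_ray_rate,
                              hot_pixel_rate = config$hot_pixel_rate,
                              hot_pixel_bin = hot_pixel_bin)
        intens[, col + j] <- s$intensities
        cb[j] <- s$cosmic_bin
        hb[j] <- s$hot_bin
      }
      meta[[r]] <- data.frame(
        spectrum_id = ids, patient_id = row$patient_id,
        specimen_id = sprintf("%s-S%02d", row$patient_id,
                              ceiling(seq_len(n) / 25)),
        class_label = row$class_label, tags = row$tags,
        acquisition_time_s = acq, n_acquisitions = nacq,
        stringsAsFactors = FALSE)
      truth[[r]] <- data.frame(
        spectrum_id = ids, patient_id = row$patient_id,
        class_label = row$class_label, profile = row$profile,
        gain = p$gain, shift = p$shift, acquisition_time_s = acq,
        cosmic_bin = cb, hot_bin = hb, stringsAsFactors = FALSE)
      col <- col + n
    }
    meta <- do.call(rbind, meta)
    truth <- do.call(rbind, truth)
    set <- newSpectraSet(intens, meta, grid, provenance = "simulate")
    list(spectra = set, truth = truth, patients = pt)
  })
}

#' Reference tissue profiles of the synthetic glioblastoma cohort
#'
#' Twelve spectral profiles built on well-known Raman bands of brain tissue:
#' a necrotic profile (cholesterol/lipid bands near 702/718 cm^-1, strong
#' amide I, high fluorescence), five vital-tumor subtypes (varying
#' nucleic-acid, phenylalanine 1004 cm^-1 and protein band mixtures),
#' gray- and white-matter profiles (the white-matter one lipid-dominated,
#' as in myelin), and four rare contaminant profiles (blood/heme, bone
#' mineral 960 cm^-1, charred tissue with broad carbon bands, and a
#' polystyrene-like foreign body) that seed small clusters and singletons.
#'
#' @return named list of [tissueProfile()] objects.
#' @export
defaultTissueProfiles <- function() {
  pk <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    lapply(seq_len(nrow(m)), function(i) peakSpec(m[i, 1], m[i, 2], m[i, 3]))
  }
  list(
    necrosis = tissueProfile("necrosis", pk(
      702, 9, 14,  718, 8, 10,  1080, 11, 12,  1302, 10, 9,
      1442, 12, 16, 1660, 14, 20), 140, 0.0012),
    vital_1 = tissueProfile("vital_1", pk(
      757, 8, 10,  1004, 6, 18,  1095, 9, 8,  1342, 10, 12, 1578, 9, 14),
      80, 0.0015),
    vital_2 = tissueProfile("vital_2", pk(
      853, 9, 9,  1004, 6, 14,  1246, 11, 10,  1450, 12, 12, 1655, 13, 15),
      70, 0.0015),
    vital_3 = tissueProfile("vital_3", pk(
      828, 8, 8,  1095, 9, 16,  1320, 10, 10,  1575, 9, 12,  1740, 10, 6),
      75, 0.0015),
    vital_4 = tissueProfile("vital_4", pk(
      936, 8, 10,  1130, 9, 8,  1208, 9, 12,  1554, 10, 10, 1615, 9, 8),
      65, 0.0015),
    vital_5 = tissueProfile("vital_5", pk(
      621, 8, 6,  1033, 8, 12,  1155, 9, 10,  1448, 12, 9,  1602, 10, 11),
      85, 0.0015),
    gray_matter = tissueProfile("gray_matter", pk(
      1004, 6, 10,  1270, 11, 12,  1440, 12, 14,  1662, 13, 12),
      60, 0.0018),
    white_matter = tissueProfile("white_matter", pk(
      700, 9, 12,  1064, 8, 16,  1296, 9, 14,  1438, 11, 18, 1658, 12, 8),
      50, 0.0018),
    hemorrhage_blood = tissueProfile("hemorrhage_blood", pk(
      754, 7, 20,  1124, 8, 10,  1374, 9, 16,  1588, 9, 18), 90, 0.0015),
    bone_chip = tissueProfile("bone_chip", pk(
      432, 10, 6,  960, 7, 30,  1070, 9, 8), 40, 0.0015),
    burnt_tissue = tissueProfile("burnt_tissue", pk(
      1350, 40, 18,  1595, 35, 20), 100, 0.0015),
    foreign_body = tissueProfile("foreign_body", pk(
      622, 7, 15,  1001, 5, 25,  1602, 7, 14), 30, 0.0015))
}

## deterministic largest-remainder split of n into weighted parts
apportion <- function(n, w) {
  raw <- n * w / sum(w)
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    o <- order(raw - k, decreasing = TRUE)
    k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1L
  }
  as.integer(k)
}

#' Study-shaped synthetic glioblastoma cohort configuration
#'
#' The default preset mirrors the cohort structure the pipeline is designed
#' for: 43 tumor patients with 1456 tumor spectra split 81 necrosis / 1304
#' vital / 71 heterogeneous, plus one autoptic control case contributing 55
#' gray-matter and 32 white-matter spectra (87 controls). Necrotic spectra
#' are concentrated in 11 patients; vital spectra come from seven abundant
#' profiles (five vital-tumor subtypes plus infiltrated gray and white
#' matter, the latter tagged `infiltration_zone`) and four rare contaminant
#' profiles (8 + 5 + 3 + 1 spectra; the blood profile tagged `hemorrhage`);
#' heterogeneous spectra mix the necrotic and vital profiles. The eleven
#' non-necrotic generating profiles are the planted ground truth against
#' which cluster recovery can be judged.
#'
#' @param seed integer RNG seed.
#' @param grid the [WavenumberGrid-class] (default 400--1800 cm^-1, 1024 bins).
#' @param profiles profile set; defaults to [defaultTissueProfiles()].
#' @param cosmic_ray_rate,hot_pixel_rate artifact rates (defaults 0.04 and
#'   0.01 per spectrum).
#' @return A [cohortConfig()] whose `generateCohort()` output has 1456 tumor
#'   and 87 control spectra.
#' @export
glioblastomaCohortConfig <- function(seed = 1L, grid = wavenumberGrid(),
                                     profiles = defaultTissueProfiles(),
                                     cosmic_ray_rate = 0.04,
                                     hot_pixel_rate = 0.01) {
  abundant <- c(vital_1 = 0.22, vital_2 = 0.18, vital_3 = 0.14,
                vital_4 = 0.10, vital_5 = 0.08, gray_matter = 0.16,
                white_matter = 0.12)
  tumor_pats <- sprintf("P%02d", 1:43)
  rows <- list()
  add <- function(pat, cl, prof, n, tags = "") {
    if (n > 0L)
      rows[[length(rows) + 1L]] <<- data.frame(
        patient_id = pat, class_label = cl, profile = prof,
        n_spectra = as.integer(n), tags = tags, stringsAsFactors = FALSE)
  }
  ## necrosis: 81 spectra over 11 patients
  nec_n <- c(8, 8, 8, 8, rep(7, 7))
  for (i in 1:11) add(tumor_pats[i], "necrosis", "necrosis", nec_n[i])
  ## rare vital contaminants: 17 spectra
  add("P12", "vital", "hemorrhage_blood", 8, tags = "hemorrhage")
  add("P13", "vital", "bone_chip", 5)
  add("P14", "vital", "burnt_tissue", 3)
  add("P15", "vital", "foreign_body", 1)
  ## abundant vital: 1287 spectra over all 43 patients
  per_pat <- rep(1287L %/% 43L, 43)
  extra <- 1287L %% 43L
  if (extra > 0) per_pat[seq_len(extra)] <- per_pat[seq_len(extra)] + 1L
  for (i in 1:43) {
    mix <- apportion(per_pat[i], abundant)
    for (k in seq_along(abundant)) {
      prof <- names(abundant)[k]
      tg <- if (prof %in% c("gray_matter", "white_matter"))
        "infiltration_zone" else ""
      add(tumor_pats[i], "vital", prof, mix[k], tags = tg)
    }
  }
  ## heterogeneous: 71 spectra over 10 patients, half necrotic profile
  het_n <- c(8, rep(7, 9))
  het_pats <- tumor_pats[16:25]
  for (i in seq_along(het_pats)) {
    n_nec <- het_n[i] %/% 2L
    add(het_pats[i], "heterogeneous", "necrosis", n_nec)
    mix <- apportion(het_n[i] - n_nec, abundant[1:3])
    for (k in 1:3)
      add(het_pats[i], "heterogeneous", names(abundant)[k], mix[k])
  }
  ## autoptic controls: one case, 55 gray + 32 white
  add("A01", "control_gray", "gray_matter", 55)
  add("A01", "control_white", "white_matter", 32)
  allocation <- do.call(rbind, rows)
  cohortConfig(grid, profiles, allocation = allocation,
               patient_gain_sd = 0.15, patient_shift_sd = 1,
               noise_sd_base = 0.6, acquisition_time_range = c(0.7, 10),
               cosmic_ray_rate = cosmic_ray_rate,
               hot_pixel_rate = hot_pixel_rate, seed = seed)
}
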