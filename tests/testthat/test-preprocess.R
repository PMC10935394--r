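test_that("a single cosmic-ray spike is restored exactly", {
  x <- matrix(1, 64, 3)
  x[20, 2] <- 100
  set <- matrixSet(x)
  out <- removeCosmicRays(set)
  expect_equal(intensities(out), matrix(1, 64, 3),
               ignore_attr = TRUE)
  rep <- S4Vectors::metadata(out)$cosmic_ray_report
  expect_equal(unname(rep$per_spectrum), c(0L, 1L, 0L))
})

test_that("spike-free Gaussian noise is essentially never corrected at z = 8", {
  withr::with_seed(21, {
    x <- matrix(rnorm(512 * 20, mean = 100, sd = 1), 512, 20)
  })
  out <- removeCosmicRays(matrixSet(x), z_threshold = 8)
  rep <- S4Vectors::metadata(out)$cosmic_ray_report
  expect_lte(rep$total_corrected / length(x), 1e-3)
})

test_that("injected cohort spikes are corrected, clean bins untouched", {
  # realistic resolution: peaks must span several bins, spikes exactly one
  coh <- twoClassCohort(seed = 31L, n_pat = 3L, n_spec = 20L,
                        n_bins = 1024L, cosmic_ray_rate = 0.5)
  raw <- intensities(coh$spectra)
  out <- intensities(removeCosmicRays(coh$spectra))
  tr <- coh$truth
  spikes <- !is.na(tr$cosmic_bin)
  hit <- mapply(function(id, bin) {
    abs(out[bin, id] - raw[bin, id]) > 1e-12
  }, tr$spectrum_id[spikes], tr$cosmic_bin[spikes])
  expect_gte(mean(hit), 0.95)
  clean_altered <- sum(abs(out - raw) > 1e-12) - sum(hit)
  expect_lte(clean_altered / length(raw), 1e-3)
})

test_that("baseline correction removes smooth background, keeps peaks in place", {
  g <- wavenumberGrid(400, 1800, 512)
  nu <- binCenters(g)
  # pure exponential background: residual below 2% of its amplitude
  bg <- 100 * exp(-0.002 * (nu - 400))
  out <- baselineCorrect(matrixSet(cbind(bg), g), 101L, 3L)
  expect_lt(max(abs(intensities(out))), 2)
  # narrow peak on zero baseline: height preserved within 5%
  pk <- 10 * exp(-0.5 * ((nu - 1000) / 10)^2)
  out <- baselineCorrect(matrixSet(cbind(pk), g), 101L, 3L)
  expect_equal(max(intensities(out)), 10, tolerance = 0.05)
  # peak position survives on peak + background, within one bin
  out <- baselineCorrect(matrixSet(cbind(pk + bg), g), 101L, 3L)
  expect_lte(abs(which.max(intensities(out)[, 1]) - which.max(pk)), 1)
  # null input is a fixed point
  out <- baselineCorrect(matrixSet(matrix(0, 512, 2), g), 101L, 3L)
  expect_equal(intensities(out), matrix(0, 512, 2), ignore_attr = TRUE)
  # invalid window geometry
  expect_error(baselineCorrect(matrixSet(cbind(bg), g), 100L, 3L),
               "configuration error")
  expect_error(baselineCorrect(matrixSet(cbind(bg), g), 5L, 7L),
               "configuration error")
})

test_that("standardization: exact column stats, stored-transform idempotence, SNV affine invariance", {
  coh <- twoClassCohort(seed = 41L)
  std <- standardizeSpectra(baselineCorrect(removeCosmicRays(coh$spectra),
                                            41L, 3L))
  x <- intensities(std)
  expect_lt(max(abs(rowMeans(x))), 1e-9)
  expect_equal(apply(x, 1, sd), rep(1, nrow(x)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # the stored transform applied to the raw input reproduces the set
  stats <- S4Vectors::metadata(std)$standardization
  again <- applyStandardization(
    baselineCorrect(removeCosmicRays(coh$spectra), 41L, 3L), stats)
  expect_equal(intensities(again), intensities(std))
  # affine-related spectra become identical after stage 1 (SNV)
  v <- withr::with_seed(5, rnorm(64))
  aff <- matrixSet(cbind(v, 3 * v + 7))
  sx <- scale(intensities(aff))
  expect_equal(sx[, 1], sx[, 2], ignore_attr = TRUE)
})

test_that("constant spectra are flagged and excluded with a warning", {
  x <- cbind(matrix(rnorm(64 * 3), 64), rep(2, 64))
  expect_warning(out <- standardizeSpectra(matrixSet(x)), "constant")
  expect_equal(ncol(out), 3L)
})

test_that("re-running a preprocessing step warns, provenance records the order", {
  coh <- twoClassCohort(seed = 51L, n_pat = 2L, n_spec = 3L)
  s1 <- removeCosmicRays(coh$spectra)
  s2 <- baselineCorrect(s1, 41L, 3L)
  s3 <- standardizeSpectra(s2)
  expect_equal(provenance(s3), c("simulate", "remove_cosmic_rays",
                                 "baseline_correct", "standardize"))
  expect_warning(removeCosmicRays(s3), "already")
})

test_that("QC dendrogram: clean two-class data passes, a saturated spectrum is flagged", {
  # homogeneous acquisition regime so no spectrum is an extreme-noise twig
  coh <- twoClassCohort(seed = 61L, n_pat = 4L, n_spec = 10L, noise = 0.3,
                        acquisition_time_range = c(5, 10))
  std <- preprocessAll(coh$spectra)
  qc <- qcDendrogram(std)
  expect_false(qc$verdict)
  expect_equal(sort(qc$levels[[1]]$branch_sizes), c(40L, 40L))
  # append one all-saturated hot-pixel spectrum and re-standardize
  raw <- intensities(coh$spectra)
  bad <- matrix(c(raw, rep(6.5e4, nrow(raw))), nrow(raw))
  md <- spectrumMeta(coh$spectra)
  md <- rbind(md, md[1, ])
  md$spectrum_id[nrow(md)] <- "SATURATED"
  set <- newSpectraSet(bad, md, spectraGrid(coh$spectra))
  qc2 <- qcDendrogram(standardizeSpectra(baselineCorrect(set, 41L, 3L)))
  expect_true(qc2$verdict)
  expect_true("SATURATED" %in% qc2$flagged)
})

test_that("QC dendrogram degenerate inputs", {
  ident <- matrixSet(matrix(1:64, 64, 4), provenance = "standardize")
  qc <- qcDendrogram(ident)
  expect_false(qc$verdict)
  expect_equal(qc$merge_heights, 0)
  expect_error(qcDendrogram(matrixSet(matrix(rnorm(64 * 3), 64),
                                      provenance = "standardize")),
               "input error")
})
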