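test_that("patient-wise split: disjoint patients, caps, determinism", {
  coh <- twoClassCohort(seed = 71L, n_pat = 6L, n_spec = 7L)
  std <- preprocessAll(coh$spectra)
  plan <- splitPatientwise(std, validation_fraction = 0.3,
                           per_patient_cap = 15L, seed = 2L)
  expect_length(intersect(plan@train_patients, plan@validation_patients), 0L)
  md <- spectrumMeta(std)
  expect_true(all(md$patient_id[md$spectrum_id %in% plan@train_ids] %in%
                  plan@train_patients))
  # cap not binding: all 7 spectra of every patient retained
  expect_equal(length(plan@train_ids) + length(plan@validation_ids),
               ncol(std))
  # cap binding: exactly 15 per patient/class, reproducible
  coh2 <- twoClassCohort(seed = 72L, n_pat = 2L, n_spec = 40L)
  std2 <- preprocessAll(coh2$spectra)
  p1 <- splitPatientwise(std2, validation_fraction = 0.5, seed = 9L)
  p2 <- splitPatientwise(std2, validation_fraction = 0.5, seed = 9L)
  expect_identical(p1@train_ids, p2@train_ids)
  tab <- table(spectrumMeta(std2)$patient_id[
    spectrumMeta(std2)$spectrum_id %in% p1@train_ids])
  expect_true(all(tab == 15L))
  # a class with a single patient cannot be split
  one <- std[, spectrumMeta(std)$patient_id %in%
               c("P01", unique(spectrumMeta(std)$patient_id[
                 spectrumMeta(std)$class_label == "vital"]))]
  keep <- spectrumMeta(one)$class_label == "vital" |
    spectrumMeta(one)$patient_id == "P01"
  expect_error(splitPatientwise(one[, keep], seed = 1),
               "single patient")
})

test_that("tuning: separable classes reach internal f1 = 1; labels permuted gives chance AUROC", {
  coh <- twoClassCohort(seed = 81L, n_pat = 5L, n_spec = 20L)
  std <- preprocessAll(coh$spectra)
  plan <- splitPatientwise(std, validation_fraction = 0.2, seed = 3L)
  grid1 <- data.frame(num_trees = 100L, max_depth = 0L,
                      mtry_frac = NA_real_)
  m <- tuneAndFit(std, plan, param_grid = grid1, n_splits = 3L,
                  n_repeats = 2L, seed = 4L)
  expect_gte(max(m@tuning$mean_f1), 0.999)
  # permutation null: shuffle class labels across patients
  md <- spectrumMeta(std)
  withr::with_seed(5, {
    perm <- md
    perm$class_label <- sample(perm$class_label)
  })
  permset <- newSpectraSet(intensities(std), perm, spectraGrid(std),
                           provenance = provenance(std))
  pplan <- splitPatientwise(permset, validation_fraction = 0.2, seed = 3L)
  mp <- suppressWarnings(tuneAndFit(permset, pplan, param_grid = grid1,
                                    n_splits = 3L, n_repeats = 2L,
                                    seed = 4L))
  expect_equal(mean(mp@cv_summary$auroc, na.rm = TRUE), 0.5,
               tolerance = 0.12)
  # grid of size 1, same seed: identical model output
  m2 <- tuneAndFit(std, plan, param_grid = grid1, n_splits = 3L,
                   n_repeats = 2L, seed = 4L)
  expect_identical(scoreSpectra(m, std), scoreSpectra(m2, std))
  expect_identical(m@threshold, m2@threshold)
})

test_that("optimal threshold: separable midpoint, brute-force agreement, error paths", {
  expect_equal(optimalThreshold(c(0.1, 0.2, 0.8, 0.9),
                                c("vital", "vital", "necrosis",
                                  "necrosis")), 0.5)
  # brute-force oracle over a dense threshold sweep, random instances
  withr::with_seed(99, {
    for (i in 1:25) {
      n <- sample(4:50, 1)
      sc <- round(runif(n), 2)
      lb <- sample(c("necrosis", "vital"), n, replace = TRUE)
      if (length(unique(lb)) < 2) lb[1:2] <- c("necrosis", "vital")
      thr <- optimalThreshold(sc, lb)
      sweep <- sort(unique(c(0, 1, sc, sc - 1e-6, sc + 1e-6)))
      best <- max(vapply(sweep, function(t)
        f1Necrosis(sc >= t, lb), numeric(1)))
      expect_equal(f1Necrosis(sc >= thr, lb), best)
    }
  })
  expect_error(optimalThreshold(c(0.1, 0.9), c("necrosis", "necrosis")),
               "both classes")
  expect_warning(t0 <- optimalThreshold(c(0.4, 0.4),
                                        c("necrosis", "vital")),
                 "degenerate")
  expect_equal(t0, 0.5)
})

test_that("metric panel: perfect scores, closed-form confusion, random-score AUROC", {
  m <- classMetrics(c(0.9, 0.95, 0.1, 0.2),
                    c("necrosis", "necrosis", "vital", "vital"), 0.5)
  expect_equal(m$accuracy, 1)
  expect_equal(m$per_class$auroc, c(1, 1))
  expect_equal(m$per_class$aupr, c(1, 1))
  expect_equal(m$per_class$misclassification_ratio, c(0, 0))
  # misclassification_ratio == 1 - recall on arbitrary confusions
  withr::with_seed(7, {
    for (i in 1:10) {
      n <- 60
      lb <- sample(c("necrosis", "vital"), n, replace = TRUE, c(0.3, 0.7))
      if (length(unique(lb)) < 2) lb[1:2] <- c("necrosis", "vital")
      sc <- runif(n)
      mm <- classMetrics(sc, lb, 0.5)
      expect_equal(mm$per_class$misclassification_ratio,
                   1 - mm$per_class$recall)
      w <- mm$per_class$support / sum(mm$per_class$support)
      expect_equal(unname(mm$weighted["f1"]), sum(mm$per_class$f1 * w))
    }
  })
  withr::with_seed(8, {
    mm <- classMetrics(runif(1000),
                       sample(c("necrosis", "vital"), 1000, TRUE), 0.5)
  })
  expect_equal(mm$per_class["necrosis", "auroc"], 0.5, tolerance = 0.05)
})

test_that("evaluation refuses any patient overlap with training", {
  coh <- twoClassCohort(seed = 91L, n_pat = 4L, n_spec = 8L)
  std <- preprocessAll(coh$spectra)
  plan <- splitPatientwise(std, validation_fraction = 0.25, seed = 1L)
  m <- tuneAndFit(std, plan,
                  param_grid = data.frame(num_trees = 50L, max_depth = 0L,
                                          mtry_frac = NA_real_),
                  n_splits = 2L, n_repeats = 1L, seed = 2L)
  expect_error(evaluateModel(m, std), "leakage")
  ev <- evaluateModel(m, std[, plan@validation_ids])
  expect_true(all(c("auroc", "aupr", "precision", "recall", "f1",
                    "misclassification_ratio") %in%
                  colnames(ev$per_class)))
})

test_that("feature importance: normalization, discriminative bin found, null is diffuse", {
  # two classes differing in exactly one bin
  base <- matrix(5, 64, 40)
  base[30, 1:20] <- 15
  withr::with_seed(3, x <- base + matrix(rnorm(64 * 40, sd = 0.05), 64))
  md <- data.frame(spectrum_id = sprintf("S%02d", 1:40),
                   patient_id = rep(sprintf("P%02d", 1:8), each = 5),
                   specimen_id = "sp", tags = "",
                   class_label = rep(c("necrosis", "vital"), each = 20),
                   acquisition_time_s = 1, n_acquisitions = 1L)
  set <- newSpectraSet(x, md, tinyGrid(), provenance = "standardize")
  plan <- splitPatientwise(set, validation_fraction = 0.25, seed = 1L)
  m <- tuneAndFit(set, plan,
                  param_grid = data.frame(num_trees = 100L, max_depth = 0L,
                                          mtry_frac = NA_real_),
                  n_splits = 2L, n_repeats = 1L, seed = 2L)
  fi <- featureImportanceReport(m, top_k = 20L)
  expect_equal(sum(fi$importance), 1, tolerance = 1e-9)
  expect_equal(which.max(fi$importance), 30L, ignore_attr = TRUE)
  expect_gt(fi$max_share, 5 / 64)        # far above the uniform share
  expect_lte(fi$top_k_share, 1)
  # identical class profiles: importance roughly uniform
  withr::with_seed(4, xn <- matrix(rnorm(64 * 40, 5, 0.5), 64))
  setn <- newSpectraSet(xn, md, tinyGrid(), provenance = "standardize")
  plann <- splitPatientwise(setn, validation_fraction = 0.25, seed = 1L)
  mn <- tuneAndFit(setn, plann,
                   param_grid = data.frame(num_trees = 100L, max_depth = 0L,
                                           mtry_frac = NA_real_),
                   n_splits = 2L, n_repeats = 1L, seed = 2L)
  fin <- featureImportanceReport(mn, top_k = 20L)
  expect_equal(fin$top_k_share, 20 / 64, tolerance = 0.5)
})
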