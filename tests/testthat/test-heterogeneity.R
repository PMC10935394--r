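test_that("re-labeling convention: score >= threshold is necrotic; counts add up", {
  coh <- twoClassCohort(seed = 15L, n_pat = 4L, n_spec = 10L)
  std <- preprocessAll(coh$spectra)
  plan <- splitPatientwise(std, validation_fraction = 0.25, seed = 1L)
  m <- tuneAndFit(std, plan,
                  param_grid = data.frame(num_trees = 100L, max_depth = 0L,
                                          mtry_frac = NA_real_),
                  n_splits = 2L, n_repeats = 1L, seed = 2L)
  rl <- relabelSpectra(m, std)
  cd <- spectrumMeta(rl)
  expect_identical(cd$spectral_label,
                   ifelse(cd$necrosis_score >= m@threshold,
                          "spectral_necrotic", "spectral_vital"))
  # boundary: a spectrum scoring exactly the threshold is necrotic
  m2 <- m
  m2@threshold <- cd$necrosis_score[1]
  if (m2@threshold > 0 && m2@threshold < 1) {
    rl2 <- spectrumMeta(relabelSpectra(m2, std))
    expect_equal(rl2$spectral_label[1], "spectral_necrotic")
  }
  cnt <- S4Vectors::metadata(rl)$relabel$counts
  expect_equal(sum(cnt), ncol(std))
  expect_equal(ncol(spectralVital(rl)), unname(cnt["spectral_vital"]))
  # well-separated necrosis is recognized as necrotic
  nec <- cd$class_label == "necrosis"
  expect_gte(mean(cd$spectral_label[nec] == "spectral_necrotic"), 0.95)
  # controls are refused
  ctrl <- std
  SummarizedExperiment::colData(ctrl)$class_label <- "control_gray"
  expect_error(relabelSpectra(m, ctrl), "control")
})

test_that("per-patient subsampling caps and is deterministic", {
  coh <- twoClassCohort(seed = 25L, n_pat = 3L, n_spec = 40L)
  s1 <- subsamplePerPatient(coh$spectra, cap = 30L, seed = 7L)
  s2 <- subsamplePerPatient(coh$spectra, cap = 30L, seed = 7L)
  expect_identical(colnames(s1), colnames(s2))
  expect_true(all(table(spectrumMeta(s1)$patient_id) <= 30L))
  # cap not binding: untouched
  s3 <- subsamplePerPatient(coh$spectra, cap = 100L, seed = 7L)
  expect_equal(ncol(s3), ncol(coh$spectra))
})

test_that("UMAP embedding separates planted classes and is seed-deterministic", {
  centers <- rbind(rep(0, 32), rep(6, 32))
  set <- blobSet(centers, n_per = 40, sd = 0.3, seed = 5L)
  emb <- embedSpectra(set, n_neighbors = 10L, seed = 11L)
  expect_true(all(is.finite(emb$x)), all(is.finite(emb$y)))
  g <- attr(set, "blob")
  c1 <- colMeans(emb[g == 1, c("x", "y")])
  c2 <- colMeans(emb[g == 2, c("x", "y")])
  spread <- mean(c(sd(emb$x[g == 1]), sd(emb$y[g == 1]),
                   sd(emb$x[g == 2]), sd(emb$y[g == 2])))
  expect_gt(sqrt(sum((c1 - c2)^2)), 3 * spread)
  emb2 <- embedSpectra(set, n_neighbors = 10L, seed = 11L)
  expect_identical(emb$x, emb2$x)
  expect_error(embedSpectra(set[, 1:5], n_neighbors = 10L), "input error")
})

test_that("WSS curve closed forms and monotonicity", {
  set <- blobSet(rbind(rep(0, 16), rep(4, 16), rep(-4, 16)),
                 n_per = c(8, 7, 6), sd = 0.5, seed = 9L)
  x <- t(intensities(set))
  expect_warning(curve <- wssCurve(set, kmax = ncol(set), n_init = 10L,
                                   seed = 2L), "truncating")
  expect_equal(unname(curve@wss[1]), sum(sweep(x, 2, colMeans(x))^2))
  expect_equal(unname(curve@wss[nrow(x)]), 0, tolerance = 1e-8)
  expect_true(all(diff(curve@wss) <= 1e-6 * curve@total_ss))
  expect_equal(vapply(curve@sizes, sum, integer(1)),
               rep(nrow(x), nrow(x)), ignore_attr = TRUE)
})

test_that("K selection: planted blobs recovered, single blob falls back to the elbow", {
  set <- blobSet(rbind(rep(0, 16), rep(5, 16), c(rep(-5, 8), rep(5, 8))),
                 n_per = 30, sd = 0.3, seed = 3L)
  curve <- wssCurve(set, kmax = 12L, n_init = 10L, seed = 4L)
  K <- selectK(curve, majority_top_m = 3L, min_minor_clusters = 0L)
  expect_equal(as.integer(K), 3L)
  expect_equal(attr(K, "method"), "majority")
  blob <- blobSet(matrix(0, 1, 16), n_per = 60, sd = 1, seed = 6L)
  bc <- wssCurve(blob, kmax = 12L, n_init = 5L, seed = 5L)
  expect_warning(Kb <- selectK(bc, majority_top_m = 3L,
                               min_minor_clusters = 3L,
                               majority_fraction = 0.9), "elbow")
  expect_equal(attr(Kb, "method"), "elbow")
})

test_that("cluster fitting: planted structure recovered, ties and determinism", {
  set <- blobSet(rbind(rep(0, 16), rep(5, 16), c(rep(-5, 8), rep(5, 8))),
                 n_per = c(40, 30, 20), sd = 0.3, seed = 13L)
  cm <- fitClusters(set, 3L, seed = 7L)
  expect_equal(mclust::adjustedRandIndex(clusterLabels(cm),
                                         attr(set, "blob")), 1)
  # cluster 1 is the largest by construction
  expect_equal(unname(which.max(tabulate(clusterLabels(cm), 3L))), 1L)
  # every spectrum sits with its nearest centroid
  x <- t(intensities(set))
  d2 <- as.matrix(dist(rbind(x, cm@centroids)))[seq_len(nrow(x)),
                                                nrow(x) + 1:3]
  expect_equal(unname(apply(d2, 1, which.min)),
               unname(clusterLabels(cm)))
  cm2 <- fitClusters(set, 3L, seed = 7L)
  expect_identical(clusterLabels(cm), clusterLabels(cm2))
  # identical points: the tie-break convention empties the second cluster
  same <- matrixSet(matrix(2, 16, 10), provenance = "standardize")
  cs <- fitClusters(same, 2L, seed = 1L)
  expect_equal(unname(table(factor(clusterLabels(cs), 1:2))[1]), 10L)
  expect_error(fitClusters(same, 11L), "input error")
})

test_that("cluster taxonomy arithmetic", {
  labels <- setNames(rep.int(1:6, c(500, 300, 100, 5, 1, 1)),
                     sprintf("S%03d", 1:907))
  cm <- handClusterModel(matrix(rnorm(6 * 16), 6), labels = labels)
  s <- summarizeClusters(cm)
  expect_equal(unname(s$sizes), c(500L, 300L, 100L, 5L, 1L, 1L))
  expect_length(s$major, 3L)
  expect_length(s$small, 1L)
  expect_length(s$singleton, 2L)
  expect_equal(s$coverage, 900 / 907)
  # all singletons
  cm1 <- handClusterModel(matrix(rnorm(3 * 16), 3),
                          labels = setNames(1:3, c("a", "b", "c")))
  s1 <- summarizeClusters(cm1)
  expect_length(s1$major, 0L)
  expect_equal(s1$coverage, 0)
})

test_that("external assignment: identity, percentages, planted concordance", {
  cen <- matrix(rnorm(9 * 32, sd = 3), 9)
  cm <- handClusterModel(cen)
  ext <- matrixSet(t(cen[c(3, 3, 5), ]), class_label = "control_gray",
                   provenance = "standardize")
  res <- assignExternal(cm, ext, standardize = FALSE)
  expect_equal(res$assignments$cluster, c(3L, 3L, 5L))
  expect_equal(res$assignments$distance, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(res$distribution$percent[res$distribution$cluster == 3], 67L)
  # grid mismatch refused
  ext2 <- matrixSet(matrix(rnorm(16 * 2), 16), provenance = "standardize")
  expect_error(assignExternal(cm, ext2, standardize = FALSE), "grid")
  # controls generated from planted profiles land in their clusters
  coh <- twoClassCohort(seed = 35L, n_pat = 4L, n_spec = 15L)
  std <- preprocessAll(coh$spectra)
  km <- fitClusters(std, 2L, seed = 3L)
  truth_cl <- spectrumMeta(std)$class_label
  modal <- vapply(1:2, function(k)
    names(which.max(table(truth_cl[clusterLabels(km) == k]))), "")
  ctrl <- twoClassCohort(seed = 36L, n_pat = 2L, n_spec = 10L)
  ctrl_pp <- baselineCorrect(removeCosmicRays(ctrl$spectra), 41L, 3L)
  asg <- assignExternal(km, ctrl_pp,
                        S4Vectors::metadata(std)$standardization)
  hit <- modal[asg$assignments$cluster] == asg$assignments$class_label
  expect_gte(mean(hit), 0.95)
})

test_that("overlap bookkeeping over designated clusters", {
  labels <- setNames(c(rep(1L, 89), rep(2L, 25), rep(3L, 67),
                       rep(4L, 100)), sprintf("S%03d", 1:281))
  tags <- c(rep("infiltration_zone", 181), rep("", 100))
  rep_ <- overlapReport(labels, tags, designated_clusters = c(1L, 2L))
  iz <- rep_$tags$infiltration_zone
  expect_equal(iz$in_designated, 114L)
  expect_equal(iz$total, 181L)
  expect_equal(iz$percent, 63L)
  expect_equal(overlapReport(labels, tags, 1:4)$tags$infiltration_zone$percent,
               100L)
  expect_equal(overlapReport(labels, tags, 99L)$tags$infiltration_zone$percent,
               0L)
  empty <- overlapReport(labels, rep("", 281), c(1L))
  expect_length(empty$tags, 0L)
})

test_that("probability overlay is a pure join", {
  coh <- twoClassCohort(seed = 45L, n_pat = 4L, n_spec = 10L)
  std <- preprocessAll(coh$spectra)
  plan <- splitPatientwise(std, validation_fraction = 0.25, seed = 1L)
  m <- tuneAndFit(std, plan,
                  param_grid = data.frame(num_trees = 50L, max_depth = 0L,
                                          mtry_frac = NA_real_),
                  n_splits = 2L, n_repeats = 1L, seed = 2L)
  rl <- relabelSpectra(m, std)
  emb <- embedSpectra(rl, n_neighbors = 10L, seed = 3L)
  ov <- necrosisProbabilityOverlay(rl, emb)
  expect_equal(nrow(ov), ncol(rl))
  expect_identical(ov$necrosis_score,
                   spectrumMeta(rl)$necrosis_score[
                     match(ov$spectrum_id, colnames(rl))])
  emb$spectrum_id[1] <- "NOPE"
  expect_error(necrosisProbabilityOverlay(rl, emb), "id mismatch")
})

test_that("clusters fit in spectral space agree with the independent embedding", {
  set <- blobSet(rbind(rep(0, 32), rep(5, 32), c(rep(-5, 16), rep(5, 16))),
                 n_per = 30, sd = 0.4, seed = 23L)
  cm <- fitClusters(set, 3L, seed = 2L)
  emb <- embedSpectra(set, n_neighbors = 10L, seed = 4L)
  sil <- cluster::silhouette(unname(clusterLabels(cm)),
                             dist(cbind(emb$x, emb$y)))
  expect_gt(mean(sil[, "sil_width"]), 0)
})
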