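#' Configuration of the end-to-end heterogeneity pipeline
#'
#' Bundles every stage parameter with its seed. Input is either a
#' `cohort_config` to simulate (the default is the study-shaped synthetic
#' preset) or an existing raw [SpectraSet-class] (tumor and control spectra
#' together; controls are recognized by their class labels).
#'
#' @param cohort a [cohortConfig()] to simulate, or `NULL` when `spectra`
#'   is given.
#' @param spectra optional raw [SpectraSet-class] instead of simulation.
#' @param truth optional ground-truth table matching `spectra`.
#' @param cosmic_z robust z cutoff of [removeCosmicRays()].
#' @param sg_window,sg_polyorder [baselineCorrect()] parameters (odd
#'   window).
#' @param binary_patients which patients enter the necrosis/vital
#'   classification: `"with_necrosis"` (patients contributing necrotic
#'   spectra, the study design) or `"all"`.
#' @param validation_fraction patient fraction held out for validation.
#' @param per_patient_cap spectra cap per patient and class for the
#'   classifier (default 15).
#' @param hyper_grid hyperparameter grid, see [defaultHyperGrid()].
#' @param cv_splits,cv_repeats internal CV geometry (default 5 x 3).
#' @param cluster_cap per-patient cap before clustering (default 30).
#' @param kmax,n_init WSS scan parameters (defaults 50 and 10).
#' @param majority_top_m,majority_fraction,min_minor_clusters [selectK()]
#'   constants.
#' @param umap_neighbors,umap_min_dist display-embedding parameters.
#' @param seed master seed; stage seeds are derived from it.
#' @return A validated `pipeline_config` list.
#' @export
pipelineConfig <- function(cohort = NULL, spectra = NULL, truth = NULL,
                           cosmic_z = 8, sg_window = 101L,
                           sg_polyorder = 3L,
                           binary_patients = c("with_necrosis", "all"),
                           validation_fraction = 3 / 11,
                           per_patient_cap = 15L,
                           hyper_grid = defaultHyperGrid(),
                           cv_splits = 5L, cv_repeats = 3L,
                           cluster_cap = 30L, kmax = 50L, n_init = 10L,
                           majority_top_m = 7L, majority_fraction = 0.9,
                           min_minor_clusters = 3L,
                           umap_neighbors = 15L, umap_min_dist = 0.1,
                           seed = 1L) {
  binary_patients <- match.arg(binary_patients)
  if (is.null(cohort) && is.null(spectra))
    stop("configuration error: give either 'cohort' or 'spectra'")
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_config"))
  if (!is.null(spectra)) stopifnot(is(spectra, "SpectraSet"))
  stopifnot(cosmic_z > 0, sg_window %% 2L == 1L,
            sg_polyorder < sg_window,
            validation_fraction > 0, validation_fraction < 1,
            per_patient_cap >= 1L, cluster_cap >= 1L, kmax >= 2L,
            n_init >= 1L, majority_fraction > 0, majority_fraction <= 1)
  seed <- as.integer(seed)
  structure(list(cohort = cohort, spectra = spectra, truth = truth,
                 cosmic_z = cosmic_z, sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 binary_patients = binary_patients,
                 validation_fraction = validation_fraction,
                 per_patient_cap = as.integer(per_patient_cap),
                 hyper_grid = hyper_grid,
                 cv_splits = as.integer(cv_splits),
                 cv_repeats = as.integer(cv_repeats),
                 cluster_cap = as.integer(cluster_cap),
                 kmax = as.integer(kmax), n_init = as.integer(n_init),
                 majority_top_m = as.integer(majority_top_m),
                 majority_fraction = majority_fraction,
                 min_minor_clusters = as.integer(min_minor_clusters),
                 umap_neighbors = as.integer(umap_neighbors),
                 umap_min_dist = umap_min_dist,
                 seeds = list(split = seed + 11L, cv = seed + 23L,
                              subsample = seed + 37L, embed = seed + 41L,
                              cluster = seed + 53L),
                 seed = seed),
            class = "pipeline_config")
}

#' Run the full heterogeneity pipeline
#'
#' Executes, in order: simulation (optional), cosmic-ray removal, baseline
#' correction, standardization, the QC dendrogram scan, patient-wise
#' splitting, random-forest tuning with repeated patient-grouped internal
#' CV, threshold-based re-labeling of the whole tumor set, per-patient
#' subsampling of the spectral-vital subset, UMAP display embedding, the
#' WSS scan with majority-criterion K selection, k-means fitting, cluster
#' taxonomy, nearest-centroid assignment of the healthy controls and the
#' infiltration-zone overlap report. Every stage is deterministic given
#' the configured seeds.
#'
#' @param config a [pipelineConfig()].
#' @param out_dir optional directory; when given, the main artifacts are
#'   written there (spectra CSVs, reports as JSON).
#' @param verbose print stage progress (default TRUE).
#' @return A `pipeline_result` list with all stage outputs (see Details)
#'   and a `manifest` recording configuration, seeds and counts.
#' @details The result carries: `cohort` (spectra/truth as simulated),
#'   `tumor` (standardized tumor set), `qc`, `plan`, `model`, `metrics`,
#'   `importance`, `relabeled`, `vital` (subsampled spectral-vital set),
#'   `embedding`, `curve`, `K`, `clusters`, `summary`, `assignment`,
#'   `designated_clusters`, `overlap`, `overlay`.
#' @export
runPipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  if (!is.null(config$cohort)) {
    say("simulating cohort (seed %d)...", config$cohort$seed)
    coh <- generateCohort(config$cohort)
    raw <- coh$spectra; truth <- coh$truth
  } else {
    raw <- config$spectra; truth <- config$truth
  }
  cls <- spectrumMeta(raw)$class_label
  is_control <- cls %in% c("control_gray", "control_white")
  tumor_raw <- raw[, !is_control]
  control_raw <- raw[, is_control]

  say("preprocessing %d tumor spectra...", ncol(tumor_raw))
  tumor <- removeCosmicRays(tumor_raw, config$cosmic_z)
  tumor <- baselineCorrect(tumor, config$sg_window, config$sg_polyorder)
  tumor <- standardizeSpectra(tumor)
  stats <- S4Vectors::metadata(tumor)$standardization
  qc <- qcDendrogram(tumor)

  say("splitting patients and fitting the classifier...")
  md <- spectrumMeta(tumor)
  bin_pats <- if (config$binary_patients == "with_necrosis")
    unique(md$patient_id[md$class_label == "necrosis"])
  else unique(md$patient_id[md$class_label %in% c("necrosis", "vital")])
  binary <- tumor[, md$patient_id %in% bin_pats &
                    md$class_label %in% c("necrosis", "vital")]
  plan <- splitPatientwise(binary,
                           validation_fraction = config$validation_fraction,
                           per_patient_cap = config$per_patient_cap,
                           seed = config$seeds$split)
  model <- tuneAndFit(binary, plan, param_grid = config$hyper_grid,
                      n_splits = config$cv_splits,
                      n_repeats = config$cv_repeats,
                      seed = config$seeds$cv)
  metrics <- evaluateModel(model, binary[, plan@validation_ids])
  importance <- featureImportanceReport(model)

  say("re-labeling at threshold %.3f...", model@threshold)
  relabeled <- relabelSpectra(model, tumor)
  vital <- spectralVital(relabeled)
  vital <- subsamplePerPatient(vital, cap = config$cluster_cap,
                               seed = config$seeds$subsample)

  say("embedding and clustering %d spectral-vital spectra...", ncol(vital))
  embedding <- embedSpectra(vital, n_neighbors = config$umap_neighbors,
                            min_dist = config$umap_min_dist,
                            seed = config$seeds$embed)
  curve <- wssCurve(vital, kmax = config$kmax, n_init = config$n_init,
                    seed = config$seeds$cluster)
  K <- selectK(curve, majority_top_m = config$majority_top_m,
               majority_fraction = config$majority_fraction,
               min_minor_clusters = config$min_minor_clusters)
  clusters <- fitClusters(vital, K, n_init = config$n_init,
                          seed = config$seeds$cluster)
  summary <- summarizeClusters(clusters)

  say("assigning %d control spectra...", ncol(control_raw))
  assignment <- designated <- overlap <- NULL
  if (ncol(control_raw) > 0L) {
    ctrl <- removeCosmicRays(control_raw, config$cosmic_z)
    ctrl <- baselineCorrect(ctrl, config$sg_window, config$sg_polyorder)
    assignment <- assignExternal(clusters, ctrl, stats)
    ## clusters the controls predominantly map to (modal cluster per class)
    dist <- assignment$distribution
    designated <- sort(unique(vapply(split(dist, dist$class_label),
      function(d) d$cluster[which.max(d$count)], integer(1L))))
    overlap <- overlapReport(clusterLabels(clusters),
                             spectrumMeta(vital)$tags, designated)
  }
  overlay <- necrosisProbabilityOverlay(relabeled, embedding)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ramahet")),
    seed = config$seed, seeds = config$seeds,
    n_tumor = ncol(tumor_raw), n_control = ncol(control_raw),
    n_spectral_vital = unname(
      S4Vectors::metadata(relabeled)$relabel$counts["spectral_vital"]),
    threshold = model@threshold, K = as.integer(K),
    selection_method = attr(K, "method"),
    runtime_s = as.numeric(Sys.time() - t0, units = "secs"))

  res <- structure(list(
    cohort = if (!is.null(config$cohort)) list(truth = truth) else NULL,
    truth = truth, tumor = tumor, qc = qc, plan = plan, model = model,
    metrics = metrics, importance = importance, relabeled = relabeled,
    vital = vital, embedding = embedding, curve = curve, K = K,
    clusters = clusters, summary = summary, assignment = assignment,
    designated_clusters = designated, overlap = overlap,
    overlay = overlay, stats = stats, config = config,
    manifest = manifest), class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeSpectra(relabeled, file.path(out_dir, "relabeled.csv"))
    utils::write.csv(overlay, file.path(out_dir, "embedding_overlay.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(K = seq_along(curve@wss), wss = unname(curve@wss)),
      file.path(out_dir, "wss_curve.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(spectrum_id = names(clusterLabels(clusters)),
                 cluster = unname(clusterLabels(clusters))),
      file.path(out_dir, "cluster_labels.csv"), row.names = FALSE)
    jsonlite::write_json(list(
      manifest = manifest,
      metrics = list(accuracy = metrics$accuracy,
                     per_class = metrics$per_class,
                     macro = as.list(metrics$macro),
                     weighted = as.list(metrics$weighted)),
      cluster_summary = list(sizes = as.list(summary$sizes),
                             coverage = summary$coverage),
      assignment = if (!is.null(assignment)) assignment$distribution,
      designated_clusters = designated),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "Heterogeneity pipeline result (seed %d, %.1f s)\n", m$seed,
    m$runtime_s))
  cat(sprintf("  %d tumor + %d control spectra; threshold %.3f; %d spectral-vital\n",
              m$n_tumor, m$n_control, m$threshold, m$n_spectral_vital))
  cat(sprintf("  validation accuracy %.3f, necrosis AUROC %.3f\n",
              x$metrics$accuracy,
              x$metrics$per_class["necrosis", "auroc"]))
  cat(sprintf("  K = %d (%s); %d major clusters, coverage %.1f%%\n",
              m$K, m$selection_method, length(x$summary$major),
              100 * x$summary$coverage))
  invisible(x)
}
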