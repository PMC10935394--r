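#' Default random-forest hyperparameter grid
#'
#' Number of trees 100/500, unlimited vs depth-20 trees, and mtry of
#' sqrt(p) (`NA`) vs 10% of the bins. Exposed so analyses can log exactly
#' which grid was searched.
#'
#' @return `data.frame` with columns `num_trees`, `max_depth` (0 =
#'   unlimited), `mtry_frac` (`NA` = sqrt(p)).
#' @export
defaultHyperGrid <- function() {
  expand.grid(num_trees = c(100L, 500L), max_depth = c(0L, 20L),
              mtry_frac = c(NA_real_, 0.1))
}

#' Patient-wise train/validation split with per-patient subsampling
#'
#' Assigns *patients* (never individual spectra) to exactly one of the two
#' splits, then subsamples each patient's spectra per class to at most
#' `per_patient_cap` without replacement. Only necrosis and vital spectra
#' participate. Both splits are guaranteed to contain at least one patient
#' of each class; if random assignment cannot achieve that, an error is
#' raised.
#'
#' @param set a [SpectraSet-class] (standardized).
#' @param validation_fraction fraction of patients assigned to the
#'   validation split (ignored when explicit lists are given).
#' @param train_patients,validation_patients optional explicit patient id
#'   vectors (must be disjoint).
#' @param per_patient_cap maximum spectra per patient and class (default 15).
#' @param seed RNG seed for patient assignment and subsampling.
#' @return A [SplitPlan-class].
#' @export
splitPatientwise <- function(set, validation_fraction = 0.3,
                             train_patients = NULL,
                             validation_patients = NULL,
                             per_patient_cap = 15L, seed = 1L) {
  stopifnot(is(set, "SpectraSet"), per_patient_cap >= 1L)
  md <- spectrumMeta(set)
  md <- md[md$class_label %in% c("necrosis", "vital"), ]
  if (nrow(md) == 0L)
    stop("input error: no necrosis/vital spectra in the set")
  for (cl in c("necrosis", "vital")) {
    npat <- length(unique(md$patient_id[md$class_label == cl]))
    if (npat > 0L && npat < 2L)
      stop("input error: class '", cl,
           "' has a single patient and cannot be split patient-wise")
  }
  pats <- unique(md$patient_id)
  withr::with_seed(as.integer(seed), {
    if (is.null(train_patients) || is.null(validation_patients)) {
      bothSplitsValid <- function(val) {
        tr <- setdiff(pats, val)
        all(vapply(c("necrosis", "vital"), function(cl) {
          p_cl <- unique(md$patient_id[md$class_label == cl])
          length(p_cl) == 0L ||
            (any(p_cl %in% tr) && any(p_cl %in% val))
        }, logical(1L)))
      }
      n_val <- max(1L, round(validation_fraction * length(pats)))
      if (n_val >= length(pats))
        stop("input error: validation_fraction leaves no training patients")
      ok <- FALSE
      for (i in 1:100) {
        val <- sample(pats, n_val)
        if (bothSplitsValid(val)) { ok <- TRUE; break }
      }
      if (!ok)
        stop("input error: could not produce a split with both classes ",
             "in both cohorts")
      validation_patients <- sort(val)
      train_patients <- sort(setdiff(pats, val))
    } else {
      if (length(intersect(train_patients, validation_patients)))
        stop("input error: train and validation patient lists overlap")
    }
    takeIds <- function(patients) {
      sub <- md[md$patient_id %in% patients, ]
      ids <- character()
      for (p in unique(sub$patient_id)) for (cl in unique(sub$class_label)) {
        block <- sub$spectrum_id[sub$patient_id == p & sub$class_label == cl]
        if (length(block) > per_patient_cap)
          block <- sample(block, per_patient_cap)
        ids <- c(ids, block)
      }
      ids
    }
    train_ids <- takeIds(train_patients)
    validation_ids <- takeIds(validation_patients)
  })
  counts <- as.data.frame(rbind(
    train = table(factor(md$class_label[md$spectrum_id %in% train_ids],
                         c("necrosis", "vital"))),
    validation = table(factor(md$class_label[md$spectrum_id %in%
                                             validation_ids],
                              c("necrosis", "vital")))))
  new("SplitPlan", train_patients = as.character(train_patients),
      validation_patients = as.character(validation_patients),
      per_patient_cap = as.integer(per_patient_cap),
      train_ids = train_ids, validation_ids = validation_ids,
      counts = counts)
}

## assign training patients to CV folds so that every fold's held-out part
## and remainder both contain necrosis and vital spectra
makePatientFolds <- function(md, n_splits, max_tries = 100L) {
  pats <- unique(md$patient_id)
  nec_pats <- unique(md$patient_id[md$class_label == "necrosis"])
  vit_pats <- unique(md$patient_id[md$class_label == "vital"])
  for (try in seq_len(max_tries)) {
    fold_of <- setNames(integer(length(pats)), pats)
    ## round-robin necrosis-bearing patients first (stratification), then rest
    ord <- c(sample(nec_pats), sample(setdiff(pats, nec_pats)))
    fold_of[ord] <- rep_len(sample(n_splits), length(ord))
    ok <- all(vapply(seq_len(n_splits), function(f) {
      te <- names(fold_of)[fold_of == f]
      tr <- setdiff(pats, te)
      any(te %in% nec_pats) && any(te %in% vit_pats) &&
        any(tr %in% nec_pats) && any(tr %in% vit_pats)
    }, logical(1L)))
    if (ok) return(fold_of)
  }
  NULL
}

rangerFit <- function(x, y, hp, seed, importance = "none") {
  mtry <- if (is.na(hp$mtry_frac)) NULL
          else max(1L, floor(hp$mtry_frac * ncol(x)))
  ranger::ranger(x = x, y = y, num.trees = hp$num_trees,
                 max.depth = hp$max_depth, mtry = mtry,
                 probability = TRUE, importance = importance,
                 num.threads = 1L, seed = seed)
}

rangerScore <- function(fit, x) {
  predict(fit, data = x, num.threads = 1L)$predictions[, "necrosis"]
}

#' Tune and fit the necrosis/vital random forest
#'
#' Hyperparameters are selected by repeated internal cross-validation
#' (default 5 splits, repeated 3 times) on the training cohort of a
#' [SplitPlan-class]. The internal folds are stratified *and*
#' patient-grouped: a patient's spectra never straddle the fold train/test
#' boundary, so the internal estimate is not inflated by patient-specific
#' signal. The grid point with the best mean internal f1 (necrosis class,
#' threshold 0.5) wins; the final forest is refit on all training spectra.
#' The pooled out-of-fold necrosis probabilities of the winning grid point
#' are kept and used to compute the f1-optimal decision threshold with
#' [optimalThreshold()] -- external validation data are never touched.
#'
#' @param set the standardized [SpectraSet-class] the plan refers to.
#' @param plan a [SplitPlan-class] from [splitPatientwise()].
#' @param param_grid hyperparameter grid, see [defaultHyperGrid()].
#' @param n_splits,n_repeats internal CV geometry (default 5 x 3).
#' @param seed RNG seed controlling folds and forests.
#' @return A [ClassifierModel-class].
#' @export
tuneAndFit <- function(set, plan, param_grid = defaultHyperGrid(),
                       n_splits = 5L, n_repeats = 3L, seed = 1L) {
  stopifnot(is(set, "SpectraSet"), is(plan, "SplitPlan"),
            nrow(param_grid) >= 1L)
  md <- spectrumMeta(set)
  md <- md[md$spectrum_id %in% plan@train_ids, ]
  if (length(unique(md$class_label)) < 2L)
    stop("input error: training cohort must contain both classes")
  X <- t(intensities(set)[, md$spectrum_id, drop = FALSE])
  colnames(X) <- sprintf("wn_%04d", seq_len(ncol(X)))
  y <- factor(md$class_label, levels = c("vital", "necrosis"))
  n_pat <- length(unique(md$patient_id))
  if (n_pat < n_splits) {
    warning("fewer training patients (", n_pat, ") than folds; reducing to ",
            n_pat, " folds", call. = FALSE)
    n_splits <- n_pat
  }
  withr::with_seed(as.integer(seed), {
    folds <- NULL
    while (is.null(folds) && n_splits >= 2L) {
      folds <- lapply(seq_len(n_repeats), function(r)
        makePatientFolds(md, n_splits))
      if (any(vapply(folds, is.null, logical(1L)))) {
        folds <- NULL
        n_splits <- n_splits - 1L
        warning("could not keep both classes on each side of every fold; ",
                "reducing to ", n_splits, " folds", call. = FALSE)
      }
    }
    if (is.null(folds))
      stop("input error: could not build internal folds with both ",
           "classes on each side")
    grid_f1 <- numeric(nrow(param_grid))
    oof_by_grid <- vector("list", nrow(param_grid))
    cv_rows <- list()
    for (g in seq_len(nrow(param_grid))) {
      hp <- param_grid[g, ]
      oof <- list()
      f1s <- c()
      for (r in seq_len(n_repeats)) {
        fold_of <- folds[[r]][md$patient_id]
        for (f in sort(unique(fold_of))) {
          te <- fold_of == f
          fit <- rangerFit(X[!te, , drop = FALSE], y[!te], hp,
                           seed = seed + 1000L * r + f)
          sc <- rangerScore(fit, X[te, , drop = FALSE])
          mm <- classMetrics(sc, as.character(y[te]), 0.5)
          f1s <- c(f1s, mm$per_class["necrosis", "f1"])
          oof[[length(oof) + 1L]] <- data.frame(
            spectrum_id = md$spectrum_id[te], rep = r, fold = f,
            score = sc, label = as.character(y[te]),
            stringsAsFactors = FALSE)
          cv_rows[[length(cv_rows) + 1L]] <- data.frame(
            grid = g, rep = r, fold = f,
            f1 = mm$per_class["necrosis", "f1"],
            auroc = mm$per_class["necrosis", "auroc"],
            accuracy = mm$accuracy)
        }
      }
      grid_f1[g] <- mean(f1s)
      oof_by_grid[[g]] <- do.call(rbind, oof)
    }
    best <- which.max(grid_f1)
    oof <- oof_by_grid[[best]]
    thr <- optimalThreshold(oof$score, oof$label)
    final <- rangerFit(X, y, param_grid[best, ], seed = seed,
                       importance = "impurity")
  })
  cv <- do.call(rbind, cv_rows)
  tuning <- cbind(param_grid, mean_f1 = grid_f1)
  std <- S4Vectors::metadata(set)$standardization
  new("ClassifierModel", forest = final, threshold = thr,
      cv_summary = cv[cv$grid == best, , drop = FALSE], tuning = tuning,
      hyperparameters = as.list(param_grid[best, ]), oof = oof,
      train_patients = plan@train_patients,
      wavenumber_fingerprint = as.numeric(wavenumbers(set)),
      standardization = if (is.null(std)) list() else std)
}

#' f1-optimal decision threshold from out-of-fold scores
#'
#' Scans every candidate threshold -- the midpoints between consecutive
#' distinct sorted scores, plus 0 and 1 -- and returns the one maximizing
#' the f1 score of the necrosis class (spectra with score >= threshold are
#' called necrotic). Ties are broken toward the lower threshold, i.e. the
#' more necrosis-sensitive rule.
#'
#' @param scores out-of-fold necrosis probabilities.
#' @param labels matching labels in `{"necrosis", "vital"}`.
#' @return The optimal threshold (a probability).
#' @examples
#' optimalThreshold(c(0.1, 0.2, 0.8, 0.9),
#'                  c("vital", "vital", "necrosis", "necrosis"))  # 0.5
#' @export
optimalThreshold <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c("necrosis", "vital")))
  if (length(unique(labels)) < 2L)
    stop("input error: both classes must be present to optimize a threshold")
  s <- sort(unique(scores))
  if (length(s) == 1L) {
    warning("degenerate scores (all equal); returning 0.5", call. = FALSE)
    return(0.5)
  }
  cands <- c(0, (s[-length(s)] + s[-1]) / 2, 1)
  f1 <- vapply(cands, function(t) {
    pred_pos <- scores >= t
    pos <- labels == "necrosis"
    f1Score(sum(pos & pred_pos), sum(!pos & pred_pos), sum(pos & !pred_pos))
  }, numeric(1L))
  cands[which.max(f1)]   # ascending candidates: first max = lowest threshold
}

#' Score spectra with a fitted classifier
#'
#' @param model a [ClassifierModel-class].
#' @param set a [SpectraSet-class] on the model's wavenumber grid,
#'   standardized with the model's stored statistics.
#' @return Named numeric vector of necrosis probabilities.
#' @export
scoreSpectra <- function(model, set) {
  stopifnot(is(model, "ClassifierModel"), is(set, "SpectraSet"))
  if (!isTRUE(all.equal(model@wavenumber_fingerprint,
                        as.numeric(wavenumbers(set)))))
    stop("grid mismatch: spectra are not on the model's wavenumber grid")
  X <- t(intensities(set))
  colnames(X) <- sprintf("wn_%04d", seq_len(ncol(X)))
  setNames(rangerScore(model@forest, X), colnames(set))
}

#' Evaluate a classifier on a held-out validation cohort
#'
#' Refuses to run if any validation patient was seen during training (the
#' leakage guard). Hard labels come from the model's stored decision
#' threshold; the full [classMetrics()] panel is returned.
#'
#' @param model a [ClassifierModel-class].
#' @param validation a standardized [SpectraSet-class] of necrosis/vital
#'   spectra from unseen patients.
#' @return A `class_metrics` list.
#' @export
evaluateModel <- function(model, validation) {
  stopifnot(is(model, "ClassifierModel"), is(validation, "SpectraSet"))
  md <- spectrumMeta(validation)
  overlap <- intersect(model@train_patients, unique(md$patient_id))
  if (length(overlap))
    stop("leakage guard: validation shares patient(s) with training: ",
         paste(overlap, collapse = ", "))
  keep <- md$class_label %in% c("necrosis", "vital")
  if (!all(keep)) validation <- validation[, keep]
  scores <- scoreSpectra(model, validation)
  classMetrics(scores, spectrumMeta(validation)$class_label,
               model@threshold)
}

#' Feature-importance report of the fitted forest
#'
#' Normalized impurity-based importance per frequency bin, the ranked bin
#' list, the cumulative share of the `top_k` most important bins and the
#' largest single-bin share. A diffuse profile (top-20 share well below 1)
#' indicates that the classification rests on broad spectral differences
#' rather than a few marker bands.
#'
#' @param model a [ClassifierModel-class] fitted with impurity importance.
#' @param top_k number of top bins to aggregate (default 20).
#' @return A `feature_importance_report` list with `importance` (named,
#'   sums to 1), `ranked` (data.frame), `top_k_share`, `max_share`.
#' @export
featureImportanceReport <- function(model, top_k = 20L) {
  stopifnot(is(model, "ClassifierModel"))
  imp <- model@forest$variable.importance
  if (is.null(imp))
    stop("model was fitted without importance; refit with impurity importance")
  imp <- pmax(imp, 0)
  if (sum(imp) == 0) imp[] <- 1
  imp <- imp / sum(imp)
  names(imp) <- format(model@wavenumber_fingerprint, trim = TRUE)
  o <- order(imp, decreasing = TRUE)
  top_k <- min(top_k, length(imp))
  structure(list(
    importance = imp,
    ranked = data.frame(rank = seq_along(imp),
                        wavenumber = model@wavenumber_fingerprint[o],
                        share = unname(imp[o])),
    top_k = top_k,
    top_k_share = sum(imp[o][seq_len(top_k)]),
    max_share = max(imp)), class = "feature_importance_report")
}

#' @export
print.feature_importance_report <- function(x, ...) {
  cat(sprintf(
    "Feature importance: top-%d bins hold %.2f%% of the contribution; max single bin %.2f%%\n",
    x$top_k, 100 * x$top_k_share, 100 * x$max_share))
  print(utils::head(x$ranked, 5), row.names = FALSE)
  invisible(x)
}
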