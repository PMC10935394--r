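#' Re-label all tumor spectra at the classifier's optimal threshold
#'
#' Every spectrum is scored with the fitted classifier and re-labeled by its
#' spectral fingerprint alone: score >= threshold -> `spectral_necrotic`,
#' otherwise `spectral_vital`. The original histological labels are kept
#' untouched; the new columns `necrosis_score` and `spectral_label` are
#' added to the metadata. Healthy-control spectra must be removed before
#' calling -- they enter the analysis later via [assignExternal()].
#'
#' @param model a [ClassifierModel-class].
#' @param set the standardized tumor [SpectraSet-class] (all histological
#'   classes, no controls).
#' @return The `SpectraSet` with scores and spectral labels;
#'   `metadata()$relabel` holds the threshold and the label counts.
#' @seealso [spectralVital()]
#' @export
relabelSpectra <- function(model, set) {
  stopifnot(is(model, "ClassifierModel"), is(set, "SpectraSet"))
  cls <- spectrumMeta(set)$class_label
  if (any(cls %in% c("control_gray", "control_white")))
    stop("control spectra must be excluded from re-labeling; ",
         "assign them to clusters with assignExternal()")
  scores <- scoreSpectra(model, set)
  lab <- ifelse(scores >= model@threshold, "spectral_necrotic",
                "spectral_vital")
  out <- set
  SummarizedExperiment::colData(out)$necrosis_score <- unname(scores)
  SummarizedExperiment::colData(out)$spectral_label <- unname(lab)
  S4Vectors::metadata(out)$relabel <- list(
    threshold = model@threshold,
    counts = c(spectral_necrotic = sum(lab == "spectral_necrotic"),
               spectral_vital = sum(lab == "spectral_vital")))
  addProvenance(out, "relabel")
}

#' @describeIn relabelSpectra the spectral-vital subset of a re-labeled set.
#' @param x a re-labeled `SpectraSet`.
#' @export
spectralVital <- function(x) {
  stopifnot(is(x, "SpectraSet"))
  lab <- SummarizedExperiment::colData(x)$spectral_label
  if (is.null(lab)) stop("set has not been re-labeled; run relabelSpectra()")
  x[, lab == "spectral_vital"]
}

#' Per-patient subsampling
#'
#' Reduces every patient's contribution to at most `cap` spectra (sampled
#' without replacement), limiting patient-specific bias before the
#' unsupervised decomposition.
#'
#' @param set a [SpectraSet-class].
#' @param cap maximum spectra per patient (default 30).
#' @param seed RNG seed.
#' @return The subsampled `SpectraSet` (original column order preserved).
#' @export
subsamplePerPatient <- function(set, cap = 30L, seed = 1L) {
  stopifnot(is(set, "SpectraSet"), cap >= 1L)
  md <- spectrumMeta(set)
  withr::with_seed(as.integer(seed), {
    keep <- unlist(lapply(split(md$spectrum_id, md$patient_id), function(ids)
      if (length(ids) > cap) sample(ids, cap) else ids), use.names = FALSE)
  })
  out <- set[, colnames(set) %in% keep]
  addProvenance(out, sprintf("subsample(cap=%d)", cap))
}

#' UMAP display embedding of standardized spectra
#'
#' Two-dimensional UMAP of the spectra for visualization. The embedding is
#' display-only: clustering always operates in the standardized spectral
#' feature space, and the agreement between the two independent views serves
#' as a control against computational artifacts.
#'
#' @param set a standardized [SpectraSet-class] with at least
#'   `n_neighbors + 1` spectra.
#' @param n_neighbors,min_dist UMAP parameters (defaults 15 and 0.1).
#' @param seed RNG seed; fixed seed gives identical coordinates.
#' @return An `embedding_result` data.frame with columns `spectrum_id`,
#'   `x`, `y`; the parameters are attached as attributes.
#' @export
embedSpectra <- function(set, n_neighbors = 15L, min_dist = 0.1,
                         seed = 42L) {
  stopifnot(is(set, "SpectraSet"))
  n <- ncol(set)
  if (n < n_neighbors + 1L)
    stop("input error: need at least n_neighbors + 1 = ", n_neighbors + 1L,
         " spectra, got ", n)
  co <- uwot::umap(t(intensities(set)), n_neighbors = n_neighbors,
                   min_dist = min_dist, metric = "euclidean",
                   n_threads = 1L, n_sgd_threads = 0L,
                   seed = as.integer(seed))
  out <- data.frame(spectrum_id = colnames(set), x = co[, 1], y = co[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "params") <- list(n_neighbors = n_neighbors,
                              min_dist = min_dist, metric = "euclidean",
                              seed = as.integer(seed))
  class(out) <- c("embedding_result", "data.frame")
  out
}

## k-means++ seeding: each next center drawn with probability proportional
## to the squared distance from the nearest chosen center
kppCenters <- function(X, K) {
  n <- nrow(X)
  idx <- integer(K)
  idx[1] <- sample.int(n, 1L)
  if (K > 1L) {
    d2 <- rowSums(sweep(X, 2L, X[idx[1], ])^2)
    for (k in 2:K) {
      d2s <- sum(d2)
      idx[k] <- if (d2s <= 0) {
        ## all remaining mass at chosen points: take any unchosen index
        sample(setdiff(seq_len(n), idx[seq_len(k - 1L)]), 1L)
      } else sample.int(n, 1L, prob = d2 / d2s)
      d2 <- pmin(d2, rowSums(sweep(X, 2L, X[idx[k], ])^2))
    }
  }
  X[idx, , drop = FALSE]
}

tryKmeans <- function(X, centers, iter.max = 50L) {
  tryCatch(suppressWarnings(kmeans(X, centers = centers,
                                   iter.max = iter.max)),
           error = function(e) NULL)
}

## best-of-n_init k-means with k-means++ seeding; optional warm start from
## the previous K's centers plus the worst-fit point, which guarantees the
## WSS curve is non-increasing in K
bestKmeans <- function(X, K, n_init, warm = NULL) {
  best <- NULL
  for (i in seq_len(n_init)) {
    km <- tryKmeans(X, kppCenters(X, K))
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
      best <- km
  }
  if (!is.null(warm) && nrow(warm$centers) == K - 1L) {
    d2 <- rowSums((X - warm$centers[warm$cluster, , drop = FALSE])^2)
    wc <- rbind(warm$centers, X[which.max(d2), ])
    if (!anyDuplicated(wc)) {
      km <- tryKmeans(X, wc)
      if (!is.null(km) && (is.null(best) ||
                           km$tot.withinss < best$tot.withinss))
        best <- km
    }
  }
  if (is.null(best)) {
    ## fewer distinct points than centers: closed-form degenerate solution
    ## (duplicate centroids; ties go to the lower cluster id downstream)
    ud <- unique(X)
    centers <- ud[rep(seq_len(nrow(ud)), length.out = K), , drop = FALSE]
    d2 <- outer(rowSums(X^2), rep(1, K)) - 2 * X %*% t(centers) +
      outer(rep(1, nrow(X)), rowSums(centers^2))
    cl <- max.col(-d2, ties.method = "first")
    best <- list(centers = centers, cluster = cl,
                 size = tabulate(cl, nbins = K),
                 tot.withinss = sum((X - centers[cl, , drop = FALSE])^2))
  }
  best
}

#' Within-cluster sum-of-squares curve over K
#'
#' For every K in 1..kmax, the inertia (WSS, squared Euclidean distance) of
#' the best of `n_init` k-means++ restarts is recorded, together with the
#' cluster sizes. Each K additionally warm-starts from the previous K's
#' solution, so the curve is non-increasing by construction. WSS(1) equals
#' the total sum of squares.
#'
#' @param set a standardized [SpectraSet-class].
#' @param kmax largest K to scan (default 50; truncated to n with a warning
#'   if n <= kmax).
#' @param n_init k-means++ restarts per K (default 10).
#' @param seed RNG seed.
#' @return A [WSSCurve-class].
#' @export
wssCurve <- function(set, kmax = 50L, n_init = 10L, seed = 1L) {
  stopifnot(is(set, "SpectraSet"), n_init >= 1L)
  X <- t(intensities(set))
  n <- nrow(X)
  if (n <= kmax) {
    warning("n (", n, ") <= kmax (", kmax, "); truncating kmax to n",
            call. = FALSE)
    kmax <- n
  }
  wss <- numeric(kmax)
  sizes <- vector("list", kmax)
  withr::with_seed(as.integer(seed), {
    prev <- NULL
    for (K in seq_len(kmax)) {
      if (K == 1L) {
        wss[1] <- sum(sweep(X, 2L, colMeans(X))^2)
        sizes[[1]] <- n
        prev <- list(centers = matrix(colMeans(X), 1L),
                     cluster = rep(1L, n))
      } else {
        km <- bestKmeans(X, K, n_init, warm = prev)
        wss[K] <- km$tot.withinss
        sizes[[K]] <- sort(as.integer(km$size), decreasing = TRUE)
        prev <- km
      }
    }
  })
  names(wss) <- as.character(seq_len(kmax))
  new("WSSCurve", wss = wss, sizes = sizes, n_init = as.integer(n_init),
      seed = as.integer(seed), total_ss = wss[[1]])
}

## elbow of a WSS curve: K with the maximum perpendicular distance to the
## chord from (1, wss[1]) to (kmax, wss[kmax])
wssElbow <- function(wss) {
  kmax <- length(wss)
  if (kmax < 3L) return(kmax)
  k <- seq_len(kmax)
  v <- c(kmax - 1, wss[kmax] - wss[1])
  v <- v / sqrt(sum(v^2))
  d <- abs((k - 1) * v[2] - (wss - wss[1]) * v[1])
  which.max(d)
}

#' Select the number of clusters from the WSS scan
#'
#' Operationalizes the majority criterion: few clusters should hold the
#' bulk of the spectra while enough clusters remain for rare spectral
#' subgroups and outliers. Starting from the WSS elbow (the curve must have
#' flattened), the smallest K is returned for which (a) the largest
#' `majority_top_m` clusters jointly hold at least `majority_fraction` of
#' the spectra and (b) at least `min_minor_clusters` clusters smaller than
#' `minor_size` spectra exist. If no K qualifies, the elbow K is returned
#' with a warning.
#'
#' @param curve a [WSSCurve-class] from [wssCurve()].
#' @param majority_top_m,majority_fraction majority criterion: the top-m
#'   clusters must cover this fraction (defaults 7 and 0.9).
#' @param min_minor_clusters minimum number of minor clusters (default 3).
#' @param minor_size cluster size below which a cluster counts as minor
#'   (default 10, the small/major cutoff of the taxonomy).
#' @return The selected K (integer, with attribute `"method"` either
#'   `"majority"` or `"elbow"`).
#' @export
selectK <- function(curve, majority_top_m = 7L, majority_fraction = 0.9,
                    min_minor_clusters = 3L, minor_size = 10L) {
  stopifnot(is(curve, "WSSCurve"))
  kmax <- length(curve@wss)
  if (kmax < 1L) stop("input error: empty WSS curve")
  n <- sum(curve@sizes[[1]])
  elbow <- as.integer(wssElbow(curve@wss))
  for (K in seq.int(elbow, kmax)) {
    sz <- curve@sizes[[K]]
    top <- sum(utils::head(sz, majority_top_m))
    if (top / n >= majority_fraction &&
        sum(sz < minor_size) >= min_minor_clusters)
      return(structure(as.integer(K), method = "majority"))
  }
  warning("no K satisfies the majority criterion; falling back to the WSS ",
          "elbow (K = ", elbow, ")", call. = FALSE)
  structure(elbow, method = "elbow")
}

#' Fit the k-means cluster model at a chosen K
#'
#' k-means (best of `n_init` k-means++ restarts) in the *standardized
#' spectral feature space* -- never in the 2-D embedding. After fitting,
#' every spectrum is re-assigned to its nearest centroid with ties broken
#' toward the lower cluster id, and clusters are renumbered by decreasing
#' size so that cluster 1 is always the largest.
#'
#' @param set a standardized [SpectraSet-class] with n >= K.
#' @param K number of clusters.
#' @param n_init restarts (default 10).
#' @param seed RNG seed.
#' @return A [ClusterModel-class].
#' @export
fitClusters <- function(set, K, n_init = 10L, seed = 1L) {
  stopifnot(is(set, "SpectraSet"), K >= 1L)
  X <- t(intensities(set))
  if (nrow(X) < K)
    stop("input error: cannot fit ", K, " clusters on ", nrow(X), " spectra")
  withr::with_seed(as.integer(seed), {
    km <- bestKmeans(X, K, n_init)
  })
  cen <- km$centers
  d2 <- outer(rowSums(X^2), rep(1, K)) - 2 * X %*% t(cen) +
    outer(rep(1, nrow(X)), rowSums(cen^2))
  lab <- max.col(-d2, ties.method = "first")
  sz <- tabulate(lab, nbins = K)
  o <- order(sz, decreasing = TRUE)       # stable: ties keep lower old id
  remap <- integer(K); remap[o] <- seq_len(K)
  lab <- remap[lab]
  cen <- cen[o, , drop = FALSE]
  rownames(cen) <- as.character(seq_len(K))
  inertia <- sum((X - cen[lab, , drop = FALSE])^2)
  new("ClusterModel", K = as.integer(K), centroids = cen,
      labels = setNames(as.integer(lab), colnames(set)),
      inertia = inertia, n_init = as.integer(n_init),
      seed = as.integer(seed), wavenumbers = as.numeric(wavenumbers(set)))
}

#' Cluster taxonomy summary
#'
#' Sizes per cluster in decreasing order and the taxonomy derived from
#' them: major clusters hold at least 10 spectra, small clusters 2--9 and
#' singletons exactly one. The coverage fraction is the share of all
#' spectra sitting in major clusters.
#'
#' @param model a [ClusterModel-class].
#' @param major_size size threshold for a major cluster (default 10).
#' @return A `cluster_summary` list: `sizes` (named, decreasing),
#'   `major`, `small`, `singleton` (cluster-id vectors), `coverage`.
#' @export
summarizeClusters <- function(model, major_size = 10L) {
  stopifnot(is(model, "ClusterModel"))
  sz <- tabulate(model@labels, nbins = model@K)
  names(sz) <- as.character(seq_len(model@K))
  sz <- sort(sz, decreasing = TRUE)
  structure(list(
    n = length(model@labels),
    sizes = sz,
    major = names(sz)[sz >= major_size],
    small = names(sz)[sz >= 2L & sz < major_size],
    singleton = names(sz)[sz == 1L],
    coverage = sum(sz[sz >= major_size]) / length(model@labels)),
    class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf(
    "Cluster taxonomy: %d clusters on %d spectra; %d major (%.1f%% coverage), %d small, %d singleton\n",
    length(x$sizes), x$n, length(x$major), 100 * x$coverage,
    length(x$small), length(x$singleton)))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Assign external spectra to the discovered clusters
#'
#' Healthy-control (or any external) spectra are standardized with the
#' *training* bin statistics -- the clustering is never refit -- and each
#' spectrum is assigned to its nearest centroid (Euclidean distance, ties
#' toward the lower cluster id). Per external class the distribution over
#' clusters is reported as counts and integer-rounded percentages.
#'
#' @param model a [ClusterModel-class].
#' @param external a [SpectraSet-class] of external spectra (preprocessed,
#'   not yet standardized when `standardize = TRUE`).
#' @param stats the training standardization statistics
#'   (`metadata()$standardization` of the training set).
#' @param standardize apply [applyStandardization()] first (default TRUE);
#'   set to FALSE if `external` is already in the training feature space.
#' @return An `assignment_result` list: `assignments` (data.frame with
#'   cluster and distance per spectrum) and `distribution` (per class and
#'   cluster: count and percent).
#' @export
assignExternal <- function(model, external, stats = NULL,
                           standardize = TRUE) {
  stopifnot(is(model, "ClusterModel"), is(external, "SpectraSet"))
  if (!isTRUE(all.equal(model@wavenumbers,
                        as.numeric(wavenumbers(external)))))
    stop("grid mismatch: external spectra are not on the model's grid")
  if (standardize) {
    if (is.null(stats))
      stop("training standardization statistics are required")
    external <- applyStandardization(external, stats)
  }
  X <- t(intensities(external))
  cen <- model@centroids
  d2 <- outer(rowSums(X^2), rep(1, model@K)) - 2 * X %*% t(cen) +
    outer(rep(1, nrow(X)), rowSums(cen^2))
  d2 <- pmax(d2, 0)
  cl <- max.col(-d2, ties.method = "first")
  md <- spectrumMeta(external)
  assignments <- data.frame(spectrum_id = md$spectrum_id,
                            class_label = md$class_label,
                            cluster = cl,
                            distance = sqrt(d2[cbind(seq_len(nrow(X)), cl)]),
                            stringsAsFactors = FALSE)
  distribution <- do.call(rbind, lapply(split(assignments,
                                              assignments$class_label),
    function(a) {
      tb <- table(a$cluster)
      data.frame(class_label = a$class_label[1],
                 cluster = as.integer(names(tb)),
                 count = as.integer(tb),
                 percent = as.integer(round(100 * as.integer(tb) / nrow(a))),
                 stringsAsFactors = FALSE)
    }))
  rownames(distribution) <- NULL
  structure(list(assignments = assignments, distribution = distribution),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("External assignment of %d spectra to %d cluster(s)\n",
              nrow(x$assignments), length(unique(x$assignments$cluster))))
  print(x$distribution, row.names = FALSE)
  invisible(x)
}

#' Histology-tag / cluster overlap report
#'
#' For every histology tag, counts the tagged spectra per cluster and the
#' fraction falling into a designated cluster set (e.g. the clusters the
#' healthy controls map to), as count/total and integer percentage.
#'
#' @param labels named integer vector of cluster labels (a
#'   [ClusterModel-class]'s `labels` slot, via [clusterLabels()]).
#' @param tags character vector of `;`-separated tags, aligned with
#'   `labels` (or named by spectrum id).
#' @param designated_clusters integer vector of designated cluster ids.
#' @return An `overlap_report` list, one entry per tag: `per_cluster`
#'   counts, `in_designated`, `total`, `percent`.
#' @export
overlapReport <- function(labels, tags, designated_clusters) {
  stopifnot(length(labels) == length(tags))
  tl <- strsplit(as.character(tags), ";", fixed = TRUE)
  all_tags <- setdiff(unique(unlist(tl)), c("", NA))
  out <- lapply(all_tags, function(tg) {
    idx <- vapply(tl, function(tt) tg %in% tt, logical(1L))
    cl <- labels[idx]
    list(tag = tg,
         per_cluster = table(cluster = cl),
         in_designated = sum(cl %in% designated_clusters),
         total = sum(idx),
         percent = as.integer(round(100 * sum(cl %in% designated_clusters) /
                                    sum(idx))))
  })
  names(out) <- all_tags
  structure(list(tags = out,
                 designated_clusters = as.integer(designated_clusters)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Tag/cluster overlap (designated clusters:",
      paste(x$designated_clusters, collapse = ", "), ")\n")
  for (t in x$tags)
    cat(sprintf("  %s: %d / %d spectra (%d%%) in designated clusters\n",
                t$tag, t$in_designated, t$total, t$percent))
  invisible(x)
}

#' @describeIn fitClusters cluster label per spectrum id.
#' @export
clusterLabels <- function(model) {
  stopifnot(is(model, "ClusterModel"))
  model@labels
}

#' Join necrosis scores onto the display embedding
#'
#' Pure bookkeeping for the probability-overlay view: joins the 2-D
#' coordinates with each spectrum's necrosis score and spectral label.
#' Every embedded spectrum must have a score; scores are carried over
#' unchanged.
#'
#' @param relabeled a re-labeled [SpectraSet-class] (see
#'   [relabelSpectra()]).
#' @param embedding an `embedding_result` from [embedSpectra()].
#' @return `data.frame` with `spectrum_id`, `x`, `y`, `necrosis_score`,
#'   `spectral_label`.
#' @export
necrosisProbabilityOverlay <- function(relabeled, embedding) {
  stopifnot(is(relabeled, "SpectraSet"), is.data.frame(embedding))
  cd <- SummarizedExperiment::colData(relabeled)
  if (is.null(cd$necrosis_score))
    stop("set has not been re-labeled; run relabelSpectra()")
  miss <- setdiff(embedding$spectrum_id, colnames(relabeled))
  if (length(miss))
    stop("id mismatch: embedded spectra missing from the re-labeled set: ",
         paste(utils::head(miss, 5), collapse = ", "))
  i <- match(embedding$spectrum_id, colnames(relabeled))
  data.frame(spectrum_id = embedding$spectrum_id,
             x = embedding$x, y = embedding$y,
             necrosis_score = cd$necrosis_score[i],
             spectral_label = cd$spectral_label[i],
             stringsAsFactors = FALSE)
}
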