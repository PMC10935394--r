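META_COLS <- c("spectrum_id", "patient_id", "specimen_id", "class_label",
               "tags", "acquisition_time_s", "n_acquisitions")

fmt17 <- function(x) sprintf("%.17g", x)   # lossless double round-trip

#' Write a SpectraSet as wide CSV with a JSON sidecar
#'
#' The canonical on-disk format: one row per spectrum with the metadata
#' columns first (`spectrum_id`, `patient_id`, `specimen_id`, `class_label`,
#' `tags`, `acquisition_time_s`, `n_acquisitions`, plus any extra columns
#' such as `necrosis_score`), then one intensity column per frequency bin
#' named by its wavenumber center. The sidecar `<path>.json` records the
#' grid, the provenance log and, if present, the standardization
#' statistics. Numbers are written with 17 significant digits so the
#' round-trip is bit-exact.
#'
#' @param set a [SpectraSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(set, path) {
  stopifnot(is(set, "SpectraSet"))
  md <- spectrumMeta(set)
  md$acquisition_time_s <- fmt17(md$acquisition_time_s)
  num_extra <- setdiff(colnames(md), META_COLS)
  for (cc in num_extra) if (is.numeric(md[[cc]])) md[[cc]] <- fmt17(md[[cc]])
  x <- t(intensities(set))
  wide <- cbind(md, as.data.frame(apply(x, 2L, fmt17),
                                  stringsAsFactors = FALSE))
  colnames(wide) <- c(colnames(md), format(wavenumbers(set), trim = TRUE))
  utils::write.table(wide, path, sep = ",", row.names = FALSE,
                     qmethod = "double")
  g <- spectraGrid(set)
  sidecar <- list(grid = list(start = g@start, end = g@end,
                              n_bins = g@n_bins),
                  provenance = provenance(set))
  std <- S4Vectors::metadata(set)$standardization
  if (!is.null(std)) sidecar$standardization <- std
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a SpectraSet from wide CSV
#'
#' Reads the format written by [writeSpectra()]. The grid comes from the
#' JSON sidecar when present, otherwise it is reconstructed from the
#' numeric column headers. Duplicate spectrum ids and non-numeric
#' intensities are rejected, malformed rows reported with their line
#' numbers.
#'
#' @param path CSV path.
#' @return A [SpectraSet-class].
#' @export
readSpectra <- function(path) {
  wide <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  miss <- setdiff(META_COLS, colnames(wide))
  if (length(miss))
    stop("parse error: missing metadata column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(wide$spectrum_id))
    stop("parse error: duplicate spectrum_id(s): ",
         paste(unique(wide$spectrum_id[duplicated(wide$spectrum_id)]),
               collapse = ", "))
  bin_cols <- setdiff(colnames(wide), META_COLS)
  bin_wn <- suppressWarnings(as.numeric(bin_cols))
  extra <- bin_cols[is.na(bin_wn)]          # non-numeric headers: extra meta
  bin_cols <- bin_cols[!is.na(bin_wn)]
  bin_wn <- bin_wn[!is.na(bin_wn)]
  sidecar_path <- paste0(path, ".json")
  std <- NULL
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    grid <- wavenumberGrid(sc$grid$start, sc$grid$end, sc$grid$n_bins)
    prov <- as.character(sc$provenance)
    std <- sc$standardization
  } else {
    grid <- wavenumberGrid(min(bin_wn), max(bin_wn), length(bin_wn))
    prov <- character()
  }
  if (grid@n_bins != length(bin_cols) ||
      !isTRUE(all.equal(binCenters(grid), bin_wn, tolerance = 1e-6)))
    stop("parse error: intensity columns inconsistent with the grid")
  x <- vapply(bin_cols, function(cc) suppressWarnings(as.numeric(wide[[cc]])),
              numeric(nrow(wide)))
  x <- matrix(x, nrow = nrow(wide))
  bad <- which(!stats::complete.cases(x))
  if (length(bad))
    stop("parse error: non-numeric intensities in data line(s) ",
         paste(utils::head(bad + 1L, 10), collapse = ", "))
  meta <- wide[c(META_COLS, extra)]
  meta$acquisition_time_s <- as.numeric(meta$acquisition_time_s)
  meta$n_acquisitions <- as.integer(meta$n_acquisitions)
  for (cc in extra) {
    v <- suppressWarnings(as.numeric(meta[[cc]]))
    if (!anyNA(v)) meta[[cc]] <- v
  }
  set <- newSpectraSet(t(x), meta, grid, provenance = prov)
  if (!is.null(std)) {
    std$bin_means <- as.numeric(std$bin_means)
    std$bin_sds <- as.numeric(std$bin_sds)
    std$wavenumbers <- as.numeric(std$wavenumbers)
    S4Vectors::metadata(set)$standardization <- std
  }
  set
}

#' Long-format conversion
#'
#' `spectraToLong()` melts a [SpectraSet-class] into a three-column table
#' (`spectrum_id`, `wavenumber`, `intensity`); `spectraFromLong()` is its
#' inverse given the per-spectrum metadata and the grid.
#'
#' @param set a [SpectraSet-class].
#' @return `spectraToLong()`: a long `data.frame`; `spectraFromLong()`: a
#'   [SpectraSet-class].
#' @export
spectraToLong <- function(set) {
  stopifnot(is(set, "SpectraSet"))
  x <- intensities(set)
  data.frame(spectrum_id = rep(colnames(x), each = nrow(x)),
             wavenumber = rep(wavenumbers(set), ncol(x)),
             intensity = as.vector(x), stringsAsFactors = FALSE)
}

#' @rdname spectraToLong
#' @param long long-format `data.frame` with columns `spectrum_id`,
#'   `wavenumber`, `intensity`.
#' @param meta per-spectrum metadata (see [newSpectraSet()]).
#' @param grid the [WavenumberGrid-class].
#' @export
spectraFromLong <- function(long, meta, grid) {
  stopifnot(all(c("spectrum_id", "wavenumber", "intensity") %in%
                colnames(long)))
  ids <- unique(long$spectrum_id)
  nb <- grid@n_bins
  if (nrow(long) != length(ids) * nb)
    stop("parse error: long table is not a complete grid x spectrum design")
  x <- matrix(NA_real_, nb, length(ids), dimnames = list(NULL, ids))
  bin <- match(round(long$wavenumber, 6), round(binCenters(grid), 6))
  if (anyNA(bin))
    stop("parse error: wavenumber(s) not on the grid")
  x[cbind(bin, match(long$spectrum_id, ids))] <- long$intensity
  meta <- meta[match(ids, meta$spectrum_id), ]
  newSpectraSet(x, meta, grid)
}
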