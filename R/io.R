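# Reading and writing centroid runs.
#
# Two interchange formats:
#   * "run-csv": one CSV per run with columns rt_min,mz,intensity (header
#     row, UTF-8).  Rows with intensity 0 and empty mz mark scans that
#     recorded no ions, so the scan grid round-trips exactly.
#   * "mzML": MS-level-1 centroid spectra via the mzR/proteowizard backend
#     (requires the mzR package).
# A cohort manifest CSV (sample_id,group,path) carries the group labels.

#' Write a cohort of centroid runs to disk
#'
#' @param runs List of `centroid_run` objects.
#' @param path Output directory (created if needed).
#' @param format `"run-csv"` or `"mzML"`.
#' @return Invisibly, the manifest file path.
#' @export
write_runs <- function(runs, path, format = c("run-csv", "mzML")) {
  format <- match.arg(format)
  stopifnot(all(vapply(runs, inherits, TRUE, "centroid_run")))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "run-csv") ".csv" else ".mzML"
  files <- character(length(runs))
  for (i in seq_along(runs)) {
    run <- runs[[i]]
    files[i] <- file.path(path, paste0(run$sample_id, ext))
    if (format == "run-csv") write_run_csv(run, files[i])
    else write_run_mzml(run, files[i])
  }
  manifest <- data.frame(
    sample_id = vapply(runs, `[[`, "", "sample_id"),
    group = vapply(runs, `[[`, "", "group"),
    path = basename(files), stringsAsFactors = FALSE)
  manifest_path <- file.path(path, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}

write_run_csv <- function(run, file) {
  ions <- run$ions
  empty <- setdiff(seq_along(run$scan_rt), unique(ions$scan))
  lines <- c("rt_min,mz,intensity",
             if (nrow(ions)) sprintf("%.6f,%.9f,%.8g",
                                     run$scan_rt[ions$scan], ions$mz,
                                     ions$intensity),
             if (length(empty)) sprintf("%.6f,,0", run$scan_rt[empty]))
  writeLines(lines, file, useBytes = TRUE)
}

read_run_csv <- function(file, sample_id, group) {
  df <- tryCatch(
    utils::read.csv(file, colClasses = c("numeric", "numeric", "numeric")),
    error = function(e) stopf("parse error in run-csv '%s': %s",
                              file, conditionMessage(e)))
  if (!identical(names(df), c("rt_min", "mz", "intensity")))
    stopf("parse error in run-csv '%s': expected header rt_min,mz,intensity",
          file)
  scan_rt <- sort(unique(df$rt_min))
  keep <- df$intensity > 0
  bad <- which(keep & !is.finite(df$mz))
  if (length(bad))
    stopf("parse error in run-csv '%s': non-finite m/z at row %d",
          file, bad[1])
  ions <- data.frame(scan = match(df$rt_min[keep], scan_rt),
                     mz = df$mz[keep], intensity = df$intensity[keep])
  ions <- ions[order(ions$scan, ions$mz), , drop = FALSE]
  rownames(ions) <- NULL
  new_centroid_run(sample_id, group, scan_rt, ions)
}

write_run_mzml <- function(run, file) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stopf("writing mzML requires the 'mzR' package")
  n <- length(run$scan_rt)
  by_scan <- split(seq_len(nrow(run$ions)), run$ions$scan)
  pk <- lapply(seq_len(n), function(i) {
    rows <- by_scan[[as.character(i)]]
    if (is.null(rows)) return(matrix(numeric(0), 0, 2,
                                     dimnames = list(NULL, c("mz", "intensity"))))
    cbind(mz = run$ions$mz[rows], intensity = run$ions$intensity[rows])
  })
  npk <- vapply(pk, nrow, 0L)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = rep(1L, n), polarity = rep(1L, n), peaksCount = npk,
    totIonCurrent = vapply(pk, function(p) sum(p[, 2]), 0),
    retentionTime = run$scan_rt * 60,
    basePeakMZ = vapply(pk, function(p)
      if (nrow(p)) p[which.max(p[, 2]), 1] else 0, 0),
    basePeakIntensity = vapply(pk, function(p)
      if (nrow(p)) max(p[, 2]) else 0, 0),
    collisionEnergy = NA_real_, ionisationEnergy = 0,
    lowMZ = vapply(pk, function(p) if (nrow(p)) min(p[, 1]) else 0, 0),
    highMZ = vapply(pk, function(p) if (nrow(p)) max(p[, 1]) else 0, 0),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = rep(TRUE, n), ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_, stringsAsFactors = FALSE)
  mzR::writeMSData(pk, file = file, header = hdr)
  invisible(file)
}

read_run_mzml <- function(file, sample_id, group) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stopf("reading mzML requires the 'mzR' package")
  handle <- mzR::openMSfile(file)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  rt <- hdr$retentionTime / 60
  inc <- diff(rt) <= 0
  if (any(inc))
    stopf("parse error in mzML '%s': retention time not increasing at scan %d",
          file, which(inc)[1] + 1L)
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  ions <- do.call(rbind, lapply(seq_along(pk), function(i) {
    p <- pk[[i]]
    if (is.null(p) || nrow(p) == 0) return(NULL)
    data.frame(scan = i, mz = p[, 1], intensity = p[, 2])
  }))
  if (is.null(ions))
    ions <- data.frame(scan = integer(0), mz = numeric(0),
                       intensity = numeric(0))
  ions <- ions[ions$intensity > 0, , drop = FALSE]
  ions <- ions[order(ions$scan, ions$mz), , drop = FALSE]
  rownames(ions) <- NULL
  new_centroid_run(sample_id, group, rt, ions)
}

#' Read a cohort of centroid runs
#'
#' @param path Directory containing a `manifest.csv`
#'   (columns `sample_id,group,path`) plus the per-run files, or the
#'   manifest file itself.
#' @return Named list of `centroid_run` objects.
#' @export
read_runs <- function(path) {
  manifest_path <- if (dir.exists(path)) file.path(path, "manifest.csv") else path
  if (!file.exists(manifest_path))
    stopf("no manifest found at '%s'", manifest_path)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group", "path") %in% names(manifest)))
    stopf("manifest '%s' must have columns sample_id, group, path",
          manifest_path)
  base_dir <- dirname(manifest_path)
  runs <- lapply(seq_len(nrow(manifest)), function(i) {
    f <- manifest$path[i]
    if (!file.exists(f)) f <- file.path(base_dir, manifest$path[i])
    if (!file.exists(f)) stopf("run file '%s' not found", manifest$path[i])
    if (grepl("\\.mzml$", f, ignore.case = TRUE))
      read_run_mzml(f, manifest$sample_id[i], manifest$group[i])
    else read_run_csv(f, manifest$sample_id[i], manifest$group[i])
  })
  names(runs) <- manifest$sample_id
  runs
}

#' Serialize ground truth to JSON
#'
#' @param truth A `ground_truth` object.
#' @param file Output JSON path.
#' @export
write_truth <- function(truth, file) {
  stopifnot(inherits(truth, "ground_truth"))
  realized_df <- as.data.frame(truth$realized)
  rownames(realized_df) <- NULL
  obj <- list(catalog = truth$catalog,
              realized = realized_df,
              sample_id = truth$sample_id, group = truth$group)
  jsonlite::write_json(obj, file, dataframe = "columns", digits = NA,
                       na = "null", pretty = TRUE)
  invisible(file)
}

#' Read ground truth from JSON
#'
#' @param file JSON path written by [write_truth()].
#' @return A `ground_truth` object (without the generating design).
#' @export
read_truth <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  catalog <- as.data.frame(obj$catalog, stringsAsFactors = FALSE)
  catalog$adduct_of <- as.character(catalog$adduct_of)
  realized <- as.matrix(as.data.frame(obj$realized))
  rownames(realized) <- catalog$id
  colnames(realized) <- obj$sample_id
  structure(list(catalog = catalog, realized = realized,
                 sample_id = obj$sample_id, group = obj$group,
                 design = NULL),
            class = "ground_truth")
}
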