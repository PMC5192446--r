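# Matrix creation from centroid runs: ROI construction by mass tolerance,
# Savitzky-Golay second-derivative peak detection, cross-sample alignment,
# intensity-threshold peak removal with a noise-elimination fallback, and
# total-ion-intensity normalization.

#' Pre-processing parameter set
#'
#' @param mass_tolerance m/z width (Da) used to group centroid ions into
#'   regions of interest; typically the instrument mass accuracy or twice it.
#' @param intensity_threshold Minimum peak height (counts) for a feature to
#'   enter the matrix: a feature is retained iff at least one sample reaches
#'   this height.
#' @param noise_elimination_level Lowered per-sample height threshold
#'   applied inside retained features (defaults to
#'   `intensity_threshold / 10`); sample values below it become missing.
#' @param align_mz_window,align_rt_window Cross-sample alignment windows
#'   (+/- Da, +/- minutes).
#' @param rt_range,mz_range Analysis windows; ions outside are ignored.
#' @param sg_window Savitzky-Golay window length in scans (odd), or
#'   `"auto"` to derive it from the estimated peak width.
#' @param sg_polyorder Savitzky-Golay polynomial order.
#' @param peak_width_5pct Expected chromatographic peak width at 5\% height
#'   in minutes, or `"auto"` to estimate it from the tallest raw EIC maxima.
#' @param baseline_threshold Minimum peak-height to baseline-noise ratio, or
#'   `"auto"` (= 3).
#' @param normalization_target Post-normalization row sum (counts).
#' @return An object of class `processing_params`.
#' @export
processing_params <- function(mass_tolerance = 0.005,
                              intensity_threshold = 10,
                              noise_elimination_level = intensity_threshold / 10,
                              align_mz_window = 0.05,
                              align_rt_window = 0.20,
                              rt_range = c(1, 15),
                              mz_range = c(100, 1000),
                              sg_window = "auto",
                              sg_polyorder = 3L,
                              peak_width_5pct = "auto",
                              baseline_threshold = "auto",
                              normalization_target = 10000) {
  if (mass_tolerance <= 0) stopf("mass_tolerance must be positive")
  if (intensity_threshold < noise_elimination_level ||
      noise_elimination_level < 0)
    stopf("need intensity_threshold >= noise_elimination_level >= 0")
  if (align_mz_window <= 0 || align_rt_window <= 0)
    stopf("alignment windows must be positive")
  if (!identical(sg_window, "auto")) {
    sg_window <- as.integer(sg_window)
    if (sg_window %% 2 == 0 || sg_window <= sg_polyorder)
      stopf("sg_window must be odd and greater than sg_polyorder")
  }
  if (!identical(baseline_threshold, "auto") && baseline_threshold < 0)
    stopf("baseline_threshold must be non-negative")
  structure(list(
    mass_tolerance = mass_tolerance,
    intensity_threshold = intensity_threshold,
    noise_elimination_level = noise_elimination_level,
    align_mz_window = align_mz_window, align_rt_window = align_rt_window,
    rt_range = as.numeric(rt_range), mz_range = as.numeric(mz_range),
    sg_window = sg_window, sg_polyorder = as.integer(sg_polyorder),
    peak_width_5pct = peak_width_5pct,
    baseline_threshold = baseline_threshold,
    normalization_target = normalization_target
  ), class = "processing_params")
}

#' Build regions of interest (ROIs) from one centroid run
#'
#' Ions with positive intensity inside the analysis windows are clustered
#' greedily in ascending m/z order: an ion joins the ROI whose running
#' intensity-weighted m/z center is within `mass_tolerance`, otherwise it
#' seeds a new ROI.  Every in-range ion is assigned to exactly one ROI.
#'
#' @param run A `centroid_run`.
#' @param params A `processing_params`.
#' @return List of ROIs: `mz_center`, `n_members`, `scan` / `intensity`
#'   vectors (intensities summed when one ROI has several ions in a scan),
#'   plus the run's scan grid attributes.
#' @export
build_rois <- function(run, params) {
  stopifnot(inherits(run, "centroid_run"), inherits(params, "processing_params"))
  ions <- run$ions
  rt <- run$scan_rt[ions$scan]
  keep <- ions$intensity > 0 &
    rt >= params$rt_range[1] & rt <= params$rt_range[2] &
    ions$mz >= params$mz_range[1] & ions$mz <= params$mz_range[2]
  ions <- ions[keep, , drop = FALSE]
  if (nrow(ions) == 0) return(list())

  ord <- order(ions$mz)
  mz <- ions$mz[ord]; inten <- ions$intensity[ord]; scan <- ions$scan[ord]
  n <- length(mz)
  roi_id <- integer(n)
  # running weighted center of the current (highest-m/z) ROI
  cur <- 0L; c_wsum <- 0; c_isum <- 0
  centers <- numeric(0)
  for (i in seq_len(n)) {
    if (cur > 0L && abs(mz[i] - c_wsum / c_isum) <= params$mass_tolerance) {
      c_wsum <- c_wsum + mz[i] * inten[i]
      c_isum <- c_isum + inten[i]
    } else {
      if (cur > 0L) centers[cur] <- c_wsum / c_isum
      cur <- cur + 1L
      c_wsum <- mz[i] * inten[i]
      c_isum <- inten[i]
    }
    roi_id[i] <- cur
  }
  centers[cur] <- c_wsum / c_isum

  idx <- split(seq_len(n), roi_id)
  rois <- lapply(seq_along(idx), function(r) {
    ii <- idx[[r]]
    # sum intensities of same-scan members
    agg <- rowsum(inten[ii], scan[ii])
    list(mz_center = centers[r],
         n_members = length(ii),
         scan = as.integer(rownames(agg)),
         intensity = as.numeric(agg[, 1]),
         member_mz = mz[ii], member_intensity = inten[ii],
         member_scan = scan[ii])
  })
  attr(rois, "scan_rt") <- run$scan_rt
  attr(rois, "sample_id") <- run$sample_id
  rois
}

# Dense EIC over the scan grid for one ROI.
roi_eic <- function(roi, n_scan) {
  eic <- numeric(n_scan)
  eic[roi$scan] <- roi$intensity
  eic
}

# Estimate the 5%-height width (in scans) of the tallest raw EIC maxima.
# Used by the "auto" mode to choose the Savitzky-Golay window.
estimate_peak_width_scans <- function(rois, n_scan, n_top = 20L) {
  heights <- vapply(rois, function(r) max(r$intensity), 0)
  top <- order(heights, decreasing = TRUE)[seq_len(min(n_top, length(rois)))]
  widths <- vapply(top, function(i) {
    eic <- roi_eic(rois[[i]], n_scan)
    apex <- which.max(eic)
    cut <- 0.05 * eic[apex]
    l <- apex; while (l > 1 && eic[l - 1] > cut) l <- l - 1
    r <- apex; while (r < n_scan && eic[r + 1] > cut) r <- r + 1
    as.numeric(r - l + 1)
  }, 0)
  stats::median(widths)
}

# Resolve "auto" detection parameters for one run's ROIs.
resolve_detection_params <- function(params, rois, n_scan, scan_interval) {
  if (identical(params$peak_width_5pct, "auto") ||
      identical(params$sg_window, "auto")) {
    w_scans <- estimate_peak_width_scans(rois, n_scan)
    if (identical(params$peak_width_5pct, "auto"))
      params$peak_width_5pct <- w_scans * scan_interval
  } else {
    w_scans <- params$peak_width_5pct / scan_interval
  }
  if (identical(params$sg_window, "auto")) {
    # window ~ half the 5%-height width: wide enough to suppress scan noise,
    # narrow enough not to distort the peak shape
    win <- max(5L, as.integer(floor(w_scans / 2)))
    if (win %% 2 == 0L) win <- win + 1L
    if (win <= params$sg_polyorder) win <- params$sg_polyorder + 2L -
        (params$sg_polyorder %% 2L)
    params$sg_window <- win
  }
  if (identical(params$baseline_threshold, "auto"))
    params$baseline_threshold <- 3
  params
}

# Cache of Savitzky-Golay filter matrices keyed by "p_n_m": building the
# local polynomial fit is far more expensive than applying it, and the same
# window is reused for every ROI of a run.
.sg_cache <- new.env(parent = emptyenv())
sg_filter <- function(p, n, m = 0) {
  key <- paste(p, n, m, sep = "_")
  f <- .sg_cache[[key]]
  if (is.null(f)) {
    f <- signal::sgolay(p = p, n = n, m = m)
    .sg_cache[[key]] <- f
  }
  f
}

empty_peaks <- function() {
  data.frame(sample_id = character(0), mz = numeric(0),
             rt_apex = numeric(0), height = numeric(0),
             area = numeric(0), width_5pct = numeric(0),
             rt_left_infl = numeric(0), rt_right_infl = numeric(0))
}

#' Detect chromatographic peaks in one ROI
#'
#' The EIC is smoothed with a Savitzky-Golay filter and its second
#' derivative is taken from the same local polynomial fit.  Candidate peaks
#' are maximal runs of negative second derivative (concave regions); the
#' run bounds serve as the inflection points and the apex is the EIC
#' maximum inside the run.  Each candidate is extended outward along the
#' smoothed trace to the nearest local minimum (the valley towards a
#' neighbouring peak, or the flat baseline), a linear baseline is drawn
#' between the integration bounds, and height (raw apex above baseline) and
#' area (trapezoidal integral of the raw trace above baseline) are
#' computed.  Candidates whose height falls below `baseline_threshold`
#' times the local baseline-noise estimate (robust SD of the
#' raw-minus-smoothed residual over the ROI neighbourhood) or below
#' `noise_elimination_level` are dropped.
#'
#' For speed the EIC is evaluated on the ROI's occupied scan span padded by
#' two smoothing windows; the rest of the grid is zero and cannot hold a
#' peak of this ROI.
#'
#' @param roi One ROI from [build_rois()].
#' @param params A `processing_params` (pass through
#'   [resolve_detection_params()] upstream, or set `sg_window`,
#'   `baseline_threshold` explicitly).
#' @param scan_rt The run's scan grid (minutes).
#' @param sample_id Sample identifier stamped on the peaks.
#' @return Data frame of peaks: `sample_id, mz, rt_apex, height, area,
#'   width_5pct, rt_left_infl, rt_right_infl`.
#' @export
detect_peaks <- function(roi, params, scan_rt, sample_id = "") {
  n_scan <- length(scan_rt)
  scan_interval <- stats::median(diff(scan_rt))
  if (identical(params$sg_window, "auto") ||
      identical(params$baseline_threshold, "auto"))
    params <- resolve_detection_params(params, list(roi), n_scan,
                                       scan_interval)
  win <- params$sg_window
  if (n_scan < win) {
    warnf("EIC shorter than the smoothing window (%d < %d): ROI at m/z %.4f skipped",
          n_scan, win, roi$mz_center)
    return(empty_peaks())
  }
  # crop to the occupied span padded by two windows (zeros elsewhere)
  lo <- max(1L, min(roi$scan) - 2L * win)
  hi <- min(n_scan, max(roi$scan) + 2L * win)
  if (hi - lo + 1L < win) {
    hi <- min(n_scan, lo + win - 1L)
    lo <- max(1L, hi - win + 1L)
  }
  eic <- numeric(hi - lo + 1L)
  eic[roi$scan - lo + 1L] <- roi$intensity
  sm <- signal::sgolayfilt(eic, sg_filter(params$sg_polyorder, win))
  d2 <- signal::sgolayfilt(eic, sg_filter(params$sg_polyorder, win, 2))
  neg <- d2 < 0
  if (!any(neg)) return(empty_peaks())

  # robust local-baseline noise from the smoothing residual
  resid <- eic - sm
  noise <- 1.4826 * stats::median(abs(resid - stats::median(resid)))

  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  n_crop <- length(eic)

  out <- vector("list", nrow(runs))
  for (k in seq_len(nrow(runs))) {
    l <- runs[k, 1]; rr <- runs[k, 2]
    apex <- l - 1L + which.max(eic[l:rr])
    if (eic[apex] <= 0) next
    lb <- l
    while (lb > 1 && sm[lb - 1] < sm[lb]) lb <- lb - 1L
    rb <- rr
    while (rb < n_crop && sm[rb + 1] < sm[rb]) rb <- rb + 1L
    if (rb <= lb) next
    base <- eic[lb] + (eic[rb] - eic[lb]) * (seq(lb, rb) - lb) / (rb - lb)
    sig <- pmax(eic[lb:rb] - base, 0)
    height <- eic[apex] - base[apex - lb + 1L]
    if (height <= 0) next
    if (noise > 0 && height < params$baseline_threshold * noise) next
    if (height < params$noise_elimination_level) next
    area <- trapz_uniform(sig, scan_interval)
    rt_crop <- scan_rt[lo:hi]
    width <- width_at_fraction(sig, rt_crop[lb:rb], apex - lb + 1L, 0.05)
    member_rel <- roi$member_scan - lo + 1L
    member_in <- member_rel >= lb & member_rel <= rb
    mz <- if (any(member_in)) {
      stats::weighted.mean(roi$member_mz[member_in],
                           roi$member_intensity[member_in])
    } else roi$mz_center
    out[[k]] <- data.frame(
      sample_id = sample_id, mz = mz, rt_apex = rt_crop[apex],
      height = height, area = area, width_5pct = width,
      rt_left_infl = rt_crop[l], rt_right_infl = rt_crop[rr],
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty_peaks())
  do.call(rbind, out)
}

# Interpolated width of a baseline-subtracted signal at `frac` of its apex.
width_at_fraction <- function(sig, rt, apex_idx, frac) {
  cut <- frac * sig[apex_idx]
  n <- length(sig)
  l <- apex_idx
  while (l > 1 && sig[l - 1] > cut) l <- l - 1
  r <- apex_idx
  while (r < n && sig[r + 1] > cut) r <- r + 1
  left_rt <- if (l > 1 && sig[l] != sig[l - 1]) {
    rt[l - 1] + (cut - sig[l - 1]) / (sig[l] - sig[l - 1]) * (rt[l] - rt[l - 1])
  } else rt[l]
  right_rt <- if (r < n && sig[r] != sig[r + 1]) {
    rt[r] + (cut - sig[r]) / (sig[r + 1] - sig[r]) * (rt[r + 1] - rt[r])
  } else rt[r]
  right_rt - left_rt
}

#' Detect peaks in every ROI of one run
#'
#' Resolves `"auto"` detection parameters once per run (peak width from the
#' 20 tallest raw EIC maxima), then runs [detect_peaks()] over all ROIs.
#'
#' @param run A `centroid_run`.
#' @param params A `processing_params`.
#' @return Data frame of peaks across all ROIs of the run.
#' @export
detect_run_peaks <- function(run, params) {
  rois <- build_rois(run, params)
  if (!length(rois)) return(empty_peaks())
  n_scan <- length(run$scan_rt)
  scan_interval <- stats::median(diff(run$scan_rt))
  params <- resolve_detection_params(params, rois, n_scan, scan_interval)
  res <- lapply(rois, detect_peaks, params = params, scan_rt = run$scan_rt,
                sample_id = run$sample_id)
  do.call(rbind, res)
}

#' Align detected peaks across samples into features
#'
#' Peaks from all runs are pooled and clustered greedily in descending
#' height order: a peak joins an existing feature if it lies within the
#' m/z and Rt alignment windows of the feature's running consensus and that
#' sample's slot is still empty (nearest feature by the scaled distance
#' `(dmz/window)^2 + (drt/window)^2` on ties); otherwise it seeds a new
#' feature.  Consensus Rt/m/z are intensity-weighted means updated
#' incrementally.  Feature ids are rendered `"<rt 2dp>_<mz 4dp>"`.
#'
#' @param peaks Data frame of peaks pooled over runs ([detect_run_peaks()]).
#' @param params A `processing_params`.
#' @param sample_ids Character vector fixing sample order (defaults to the
#'   order of appearance).
#' @return An `aligned_features` object: `features` data frame
#'   (`feature_id, rt, mz`) and `heights` matrix (samples x features, NA
#'   where a sample contributed no peak).
#' @export
align_peaks <- function(peaks, params, sample_ids = unique(peaks$sample_id)) {
  stopifnot(nrow(peaks) >= 1)
  ord <- order(peaks$height, decreasing = TRUE)
  pk_mz <- peaks$mz[ord]; pk_rt <- peaks$rt_apex[ord]
  pk_h <- peaks$height[ord]
  pk_samp <- match(peaks$sample_id[ord], sample_ids)
  n_samp <- length(sample_ids)
  wm <- params$align_mz_window; wr <- params$align_rt_window

  n_pk <- length(pk_mz)
  f_mz <- numeric(n_pk); f_rt <- numeric(n_pk)  # consensus (upper bound size)
  f_wsum_mz <- numeric(n_pk); f_wsum_rt <- numeric(n_pk); f_w <- numeric(n_pk)
  nf <- 0L
  hmat <- matrix(NA_real_, n_samp, n_pk)
  bins <- new.env(parent = emptyenv())  # m/z-bin -> feature indices

  bin_of <- function(mz) as.character(floor(mz / wm))
  for (i in seq_len(n_pk)) {
    b <- floor(pk_mz[i] / wm)
    cand <- c(bins[[as.character(b - 1)]], bins[[as.character(b)]],
              bins[[as.character(b + 1)]])
    hit <- 0L
    if (length(cand)) {
      dmz <- abs(f_mz[cand] - pk_mz[i])
      drt <- abs(f_rt[cand] - pk_rt[i])
      ok <- dmz <= wm & drt <= wr & is.na(hmat[pk_samp[i], cand])
      if (any(ok)) {
        d <- (dmz[ok] / wm)^2 + (drt[ok] / wr)^2
        hit <- cand[ok][which.min(d)]
      }
    }
    if (hit == 0L) {
      nf <- nf + 1L
      hit <- nf
      key <- bin_of(pk_mz[i])
      bins[[key]] <- c(bins[[key]], nf)
    }
    f_wsum_mz[hit] <- f_wsum_mz[hit] + pk_mz[i] * pk_h[i]
    f_wsum_rt[hit] <- f_wsum_rt[hit] + pk_rt[i] * pk_h[i]
    f_w[hit] <- f_w[hit] + pk_h[i]
    f_mz[hit] <- f_wsum_mz[hit] / f_w[hit]
    f_rt[hit] <- f_wsum_rt[hit] / f_w[hit]
    hmat[pk_samp[i], hit] <- pk_h[i]
  }

  features <- data.frame(
    feature_id = sprintf("%.2f_%.4f", f_rt[seq_len(nf)], f_mz[seq_len(nf)]),
    rt = f_rt[seq_len(nf)], mz = f_mz[seq_len(nf)],
    stringsAsFactors = FALSE)
  hmat <- hmat[, seq_len(nf), drop = FALSE]
  rownames(hmat) <- sample_ids
  colnames(hmat) <- features$feature_id
  structure(list(features = features, heights = hmat,
                 sample_ids = sample_ids, params = params),
            class = "aligned_features")
}

#' Apply the intensity threshold with noise-elimination fallback
#'
#' A feature is retained iff its maximum per-sample height reaches
#' `intensity_threshold`.  Within a retained feature the per-sample
#' threshold is lowered to `noise_elimination_level`: sample heights at or
#' above it are kept, heights below become missing.
#'
#' @param aligned An `aligned_features` object.
#' @param params A `processing_params`.
#' @return The filtered `aligned_features`.
#' @export
apply_intensity_threshold <- function(aligned, params) {
  stopifnot(inherits(aligned, "aligned_features"))
  h <- aligned$heights
  fmax <- apply(h, 2, max, na.rm = TRUE)
  keep <- fmax >= params$intensity_threshold
  h <- h[, keep, drop = FALSE]
  h[!is.na(h) & h < params$noise_elimination_level] <- NA_real_
  aligned$heights <- h
  aligned$features <- aligned$features[keep, , drop = FALSE]
  aligned$params <- params
  aligned
}

#' Normalize each sample to a constant total ion intensity
#'
#' Rescales every sample's non-missing feature heights so that they sum to
#' `normalization_target`; missing cells stay missing.
#'
#' @param aligned An `aligned_features` object (post-threshold).
#' @param groups Named character vector (or vector in sample order) of
#'   group labels.
#' @return A `feature_table`: `values` (samples x features, normalized),
#'   `sample_id`, `group`, `features` metadata and provenance `params`.
#' @export
normalize_total_intensity <- function(aligned, groups) {
  stopifnot(inherits(aligned, "aligned_features"))
  h <- aligned$heights
  if (ncol(h) == 0) stopf("no features to normalize")
  if (!is.null(names(groups))) groups <- groups[aligned$sample_ids]
  sums <- rowSums(h, na.rm = TRUE)
  zero <- sums == 0
  if (any(zero))
    stopf("sample '%s' has zero total intensity; cannot normalize",
          aligned$sample_ids[which(zero)[1]])
  target <- aligned$params$normalization_target
  values <- h * (target / sums)
  structure(list(values = values, sample_id = aligned$sample_ids,
                 group = as.character(groups), features = aligned$features,
                 params = aligned$params),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d samples (%s) x %d features; %.1f%% missing\n",
              nrow(x$values), paste(names(table(x$group)),
                                    table(x$group), sep = "=", collapse = ", "),
              ncol(x$values), 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Run the full matrix-creation stage over a cohort
#'
#' ROI construction and peak detection per run, alignment across runs,
#' intensity thresholding and total-ion-intensity normalization.
#'
#' @param runs List of `centroid_run` objects.
#' @param params A `processing_params`.
#' @return A `feature_table`.
#' @export
process_cohort <- function(runs, params) {
  peaks <- do.call(rbind, lapply(runs, detect_run_peaks, params = params))
  if (is.null(peaks) || nrow(peaks) == 0)
    stopf("no peaks detected in any run")
  sample_ids <- vapply(runs, `[[`, "", "sample_id")
  groups <- stats::setNames(vapply(runs, `[[`, "", "group"), sample_ids)
  aligned <- align_peaks(peaks, params, sample_ids = sample_ids)
  aligned <- apply_intensity_threshold(aligned, params)
  normalize_total_intensity(aligned, groups)
}

#' Flag features not explained by the synthetic ground truth
#'
#' A feature is truth-matched when a catalog entry lies within the
#' alignment windows of its consensus (Rt, m/z); remaining features are
#' noise-flagged.  Synthetic-harness diagnostic only.
#'
#' @param table A `feature_table` (or `aligned_features`).
#' @param truth A `ground_truth`.
#' @return Logical vector, TRUE where the feature matches no catalog entry.
#' @export
noise_flags <- function(table, truth) {
  feats <- table$features
  wm <- table$params$align_mz_window
  wr <- table$params$align_rt_window
  vapply(seq_len(nrow(feats)), function(i) {
    !any(abs(truth$catalog$mz_center - feats$mz[i]) <= wm &
           abs(truth$catalog$rt_center - feats$rt[i]) <= wr)
  }, TRUE)
}
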