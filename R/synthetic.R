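# Synthetic centroid LC-MS cohort generator with planted ground truth.
#
# The generator emulates a two-group (control vs treated) positive-mode
# centroid acquisition: Gaussian chromatographic peaks on a regular scan
# grid, per-scan centroid m/z jitter, lognormal between-sample biological
# variation, group-differential ("discriminating") metabolites with known
# fold changes, sodium-adduct companion ions, and uniform sub-threshold
# chemical-noise ions.  Every above-noise ion traces back to a catalog
# entry, so peak detection, alignment, thresholding and feature selection
# can all be scored against truth.

MZ_NA_H_SHIFT <- 21.9819  # Da, [M+Na]+ minus [M+H]+

#' Build a synthetic cohort design
#'
#' Fills in and validates the parameters of a synthetic centroid LC-MS
#' cohort.  Defaults mirror the study design the package's sensitivity
#' experiment is modelled on: 9 control and 15 treated samples, m/z
#' 100--1000 Da, retention time 1--15 min.
#'
#' @param n_control,n_treated Number of samples per group (each >= 3 so
#'   that seven-fold cross-validation is constructible downstream).
#' @param rt_range,mz_range Acquisition windows, minutes and Da.
#' @param scan_interval Scan spacing in minutes.  The default 0.005 min
#'   makes a 0.05 min-wide chromatographic peak span >= 10 scans.
#' @param n_background_metabolites,n_discriminating_metabolites Catalog
#'   sizes for shared and group-differential metabolites.
#' @param fold_changes Treated/control expected intensity ratio, recycled
#'   to one value per discriminating metabolite.  Must be positive.
#' @param peak_sigma_rt Gaussian chromatographic peak SD, minutes.
#' @param mz_jitter_sd Per-scan centroid mass error SD, Da (truncated at
#'   4 SD, reflecting a bounded calibrated mass-accuracy window).
#' @param intensity_cv Between-sample biological coefficient of variation
#'   (lognormal multiplicative noise with mean 1).
#' @param n_latent_factors,latent_variance_share Correlation structure of
#'   the biological variation: each metabolite belongs to one of
#'   `n_latent_factors` latent co-regulation groups (pathway-like blocks),
#'   and `latent_variance_share` of its log-intensity noise variance is a
#'   factor effect shared by the whole block in a given sample.  Metabolite
#'   intensities in real extracts co-vary strongly; without this structure
#'   a permuted-label discriminant model could fit the (then effectively
#'   full-rank) matrix almost perfectly in-sample.
#' @param noise_ion_density Expected chemical-noise ions per scan.
#' @param noise_intensity_range Uniform intensity range of noise ions,
#'   counts; chosen to sit mostly below typical intensity thresholds.
#' @param adduct_probability Probability that a metabolite carries a
#'   correlated [M+Na]+ companion ion at +21.9819 Da.
#' @param adduct_intensity_ratio Adduct/parent intensity ratio: either a
#'   fixed scalar or a `c(lo, hi)` range from which each adduct's ratio is
#'   drawn log-uniformly (adduct formation efficiency varies widely between
#'   compounds, which places some redundant ions near the detection and
#'   selection boundaries).
#' @param base_intensity_meanlog,base_intensity_sdlog Lognormal parameters
#'   of background-metabolite apex intensities (counts).
#' @param disc_intensity_range Log-uniform range of discriminating
#'   metabolite control-group apex intensities (counts).  Kept a minor
#'   share of the total ion current (as induced secondary metabolites
#'   typically are) so that total-intensity normalization does not imprint
#'   the planted effects onto every background feature (closure artifact).
#' @param seed Integer RNG seed; identical designs generate identical
#'   cohorts.
#'
#' @return An object of class `synthetic_design`.
#' @export
build_design <- function(n_control = 9L,
                         n_treated = 15L,
                         rt_range = c(1, 15),
                         mz_range = c(100, 1000),
                         scan_interval = 0.005,
                         n_background_metabolites = 190L,
                         n_discriminating_metabolites = 10L,
                         fold_changes = 8,
                         peak_sigma_rt = 0.02,
                         mz_jitter_sd = 0.001,
                         intensity_cv = 0.2,
                         n_latent_factors = 5L,
                         latent_variance_share = 0.5,
                         noise_ion_density = 0.2,
                         noise_intensity_range = c(1, 30),
                         adduct_probability = 0.3,
                         adduct_intensity_ratio = c(0.05, 0.5),
                         base_intensity_meanlog = log(300),
                         base_intensity_sdlog = 1.0,
                         disc_intensity_range = c(50, 300),
                         seed = 20161103L) {
  chk_count <- function(x, nm, min = 0L) {
    if (length(x) != 1 || !is.finite(x) || x < min || x != round(x))
      stopf("invalid design field '%s': must be a single integer >= %d", nm, min)
    as.integer(x)
  }
  chk_range <- function(x, nm, positive = FALSE) {
    if (length(x) != 2 || any(!is.finite(x)) || x[1] >= x[2] ||
        (positive && x[1] < 0))
      stopf("invalid design field '%s': must be an increasing pair", nm)
    as.numeric(x)
  }
  chk_pos <- function(x, nm, strict = TRUE) {
    if (length(x) != 1 || !is.finite(x) || (if (strict) x <= 0 else x < 0))
      stopf("invalid design field '%s': must be %s", nm,
            if (strict) "positive" else "non-negative")
    as.numeric(x)
  }

  n_control <- chk_count(n_control, "n_control", 3L)
  n_treated <- chk_count(n_treated, "n_treated", 3L)
  n_background_metabolites <-
    chk_count(n_background_metabolites, "n_background_metabolites", 0L)
  n_discriminating_metabolites <-
    chk_count(n_discriminating_metabolites, "n_discriminating_metabolites", 0L)
  rt_range <- chk_range(rt_range, "rt_range")
  mz_range <- chk_range(mz_range, "mz_range", positive = TRUE)
  scan_interval <- chk_pos(scan_interval, "scan_interval")
  peak_sigma_rt <- chk_pos(peak_sigma_rt, "peak_sigma_rt")
  mz_jitter_sd <- chk_pos(mz_jitter_sd, "mz_jitter_sd", strict = FALSE)
  intensity_cv <- chk_pos(intensity_cv, "intensity_cv", strict = FALSE)
  n_latent_factors <- chk_count(n_latent_factors, "n_latent_factors", 1L)
  if (length(latent_variance_share) != 1 ||
      !is.finite(latent_variance_share) ||
      latent_variance_share < 0 || latent_variance_share >= 1)
    stopf("invalid design field 'latent_variance_share': must be in [0, 1)")
  noise_ion_density <- chk_pos(noise_ion_density, "noise_ion_density",
                               strict = FALSE)
  noise_intensity_range <- chk_range(noise_intensity_range,
                                     "noise_intensity_range", positive = TRUE)
  if (length(adduct_probability) != 1 || !is.finite(adduct_probability) ||
      adduct_probability < 0 || adduct_probability > 1)
    stopf("invalid design field 'adduct_probability': must be in [0, 1]")
  if (length(adduct_intensity_ratio) == 1) {
    adduct_intensity_ratio <- chk_pos(adduct_intensity_ratio,
                                      "adduct_intensity_ratio")
  } else {
    adduct_intensity_ratio <- chk_range(adduct_intensity_ratio,
                                        "adduct_intensity_ratio",
                                        positive = TRUE)
  }
  disc_intensity_range <- chk_range(disc_intensity_range,
                                    "disc_intensity_range", positive = TRUE)
  if (n_discriminating_metabolites > 0) {
    fold_changes <- rep_len(as.numeric(fold_changes),
                            n_discriminating_metabolites)
    if (any(!is.finite(fold_changes)) || any(fold_changes <= 0))
      stopf("invalid design field 'fold_changes': must be positive")
  } else {
    fold_changes <- numeric(0)
  }
  seed <- chk_count(seed, "seed", 0L)

  structure(list(
    n_control = n_control, n_treated = n_treated,
    rt_range = rt_range, mz_range = mz_range,
    scan_interval = scan_interval,
    n_background_metabolites = n_background_metabolites,
    n_discriminating_metabolites = n_discriminating_metabolites,
    fold_changes = fold_changes,
    peak_sigma_rt = peak_sigma_rt, mz_jitter_sd = mz_jitter_sd,
    intensity_cv = intensity_cv,
    n_latent_factors = n_latent_factors,
    latent_variance_share = latent_variance_share,
    noise_ion_density = noise_ion_density,
    noise_intensity_range = noise_intensity_range,
    adduct_probability = adduct_probability,
    adduct_intensity_ratio = adduct_intensity_ratio,
    base_intensity_meanlog = base_intensity_meanlog,
    base_intensity_sdlog = base_intensity_sdlog,
    disc_intensity_range = disc_intensity_range,
    seed = seed
  ), class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf(
    paste0("Synthetic LC-MS cohort design\n",
           "  samples: %d control + %d treated\n",
           "  Rt %g-%g min (scan every %g min), m/z %g-%g Da\n",
           "  metabolites: %d background + %d discriminating",
           " (fold change %s)\n",
           "  noise: %g ions/scan in [%g, %g] counts;",
           " adduct probability %g; CV %g; seed %d\n"),
    x$n_control, x$n_treated, x$rt_range[1], x$rt_range[2], x$scan_interval,
    x$mz_range[1], x$mz_range[2], x$n_background_metabolites,
    x$n_discriminating_metabolites,
    paste(unique(signif(x$fold_changes, 3)), collapse = "/"),
    x$noise_ion_density, x$noise_intensity_range[1],
    x$noise_intensity_range[2], x$adduct_probability, x$intensity_cv,
    x$seed))
  invisible(x)
}

# Draw the metabolite catalog: positions, base intensities, adducts.
draw_catalog <- function(design) {
  n_bg <- design$n_background_metabolites
  n_disc <- design$n_discriminating_metabolites
  n <- n_bg + n_disc
  rt_margin <- 4 * design$peak_sigma_rt + 0.1
  rt_lo <- design$rt_range[1] + rt_margin
  rt_hi <- design$rt_range[2] - rt_margin
  mz_lo <- design$mz_range[1] + 1
  mz_hi <- design$mz_range[2] - MZ_NA_H_SHIFT - 1

  rt_center <- stats::runif(n, rt_lo, rt_hi)
  mz_center <- stats::runif(n, mz_lo, mz_hi)
  is_disc <- c(rep(FALSE, n_bg), rep(TRUE, n_disc))
  base <- numeric(n)
  if (n_bg > 0)
    base[!is_disc] <- stats::rlnorm(n_bg, design$base_intensity_meanlog,
                                    design$base_intensity_sdlog)
  if (n_disc > 0)
    base[is_disc] <- exp(stats::runif(n_disc,
                                      log(design$disc_intensity_range[1]),
                                      log(design$disc_intensity_range[2])))
  fold <- rep(1, n)
  fold[is_disc] <- design$fold_changes

  catalog <- data.frame(
    id = sprintf("M%03d", seq_len(n)),
    rt_center = rt_center, mz_center = mz_center,
    base_intensity = base, is_discriminating = is_disc,
    fold_change = fold, adduct_of = NA_character_,
    latent_factor = sample.int(design$n_latent_factors, n, replace = TRUE),
    stringsAsFactors = FALSE)

  has_adduct <- stats::runif(n) < design$adduct_probability
  catalog$adduct_ratio <- NA_real_
  if (any(has_adduct)) {
    add <- catalog[has_adduct, , drop = FALSE]
    r <- design$adduct_intensity_ratio
    add$adduct_ratio <- if (length(r) == 2)
      exp(stats::runif(nrow(add), log(r[1]), log(r[2]))) else r
    add$adduct_of <- add$id
    add$id <- paste0(add$id, "_Na")
    add$mz_center <- add$mz_center + MZ_NA_H_SHIFT
    add$base_intensity <- add$base_intensity * add$adduct_ratio
    catalog <- rbind(catalog, add)
  }
  rownames(catalog) <- NULL
  catalog
}

#' Generate a synthetic centroid LC-MS cohort with ground truth
#'
#' Realizes a [build_design()] into one centroid run per sample plus the
#' generating ground truth.  Each catalog metabolite appears as a Gaussian
#' chromatographic peak (apex height = the sample's realized intensity, SD
#' = `peak_sigma_rt`, truncated at 4 SD) whose per-scan centroid m/z is the
#' catalog m/z plus truncated-Gaussian jitter.  Treated-group expected
#' intensities of discriminating metabolites are `fold_change` times the
#' control expectation; between-sample variation is lognormal with mean 1
#' and the design's CV.  Adduct ions inherit their parent's realized
#' intensity exactly (perfectly correlated before measurement noise).
#' Chemical-noise ions are drawn per scan at the design's density, uniform
#' in m/z and intensity.
#'
#' @param design A `synthetic_design` from [build_design()].
#' @return A list with `runs` (list of `centroid_run`) and `truth`
#'   (`ground_truth`: the catalog plus the per-sample realized apex
#'   intensities, metabolites x samples).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  with_seed(design$seed, {
    catalog <- draw_catalog(design)
    n_samp <- design$n_control + design$n_treated
    sample_id <- sprintf("S%02d", seq_len(n_samp))
    group <- c(rep("C", design$n_control), rep("T", design$n_treated))

    # Realized apex intensities: base * fold^(treated) * lognormal(mean 1),
    # with the log-noise split into a latent block factor shared by the
    # metabolite's co-regulation group and an individual residual.
    sdlog <- sqrt(log(1 + design$intensity_cv^2))
    sd_shared <- sdlog * sqrt(design$latent_variance_share)
    sd_indiv <- sdlog * sqrt(1 - design$latent_variance_share)
    parent_idx <- match(catalog$adduct_of, catalog$id)
    n_cat <- nrow(catalog)
    realized <- matrix(0, n_cat, n_samp,
                       dimnames = list(catalog$id, sample_id))
    is_parent <- is.na(catalog$adduct_of)
    for (s in seq_len(n_samp)) {
      mu <- catalog$base_intensity *
        (if (group[s] == "T") catalog$fold_change else rep(1, n_cat))
      z <- stats::rnorm(design$n_latent_factors)
      eps <- stats::rnorm(n_cat)
      noise <- exp(sd_shared * z[catalog$latent_factor] + sd_indiv * eps -
                     sdlog^2 / 2)
      val <- mu * noise
      # adducts track their parent's realization exactly (r = 1)
      adj <- which(!is_parent)
      if (length(adj))
        val[adj] <- val[parent_idx[adj]] * catalog$adduct_ratio[adj]
      realized[, s] <- val
    }

    scan_rt <- seq(design$rt_range[1], design$rt_range[2],
                   by = design$scan_interval)
    n_scan <- length(scan_rt)

    runs <- vector("list", n_samp)
    for (s in seq_len(n_samp)) {
      ion_list <- vector("list", n_cat + 1L)
      for (m in seq_len(n_cat)) {
        rt0 <- catalog$rt_center[m]
        sig <- design$peak_sigma_rt
        idx <- which(abs(scan_rt - rt0) <= 4 * sig)
        if (!length(idx)) next
        inten <- realized[m, s] * exp(-(scan_rt[idx] - rt0)^2 / (2 * sig^2))
        mz <- catalog$mz_center[m] +
          rnorm_trunc(length(idx), design$mz_jitter_sd)
        ion_list[[m]] <- data.frame(scan = idx, mz = mz, intensity = inten)
      }
      n_noise <- stats::rpois(1, design$noise_ion_density * n_scan)
      if (n_noise > 0) {
        ion_list[[n_cat + 1L]] <- data.frame(
          scan = sample.int(n_scan, n_noise, replace = TRUE),
          mz = stats::runif(n_noise, design$mz_range[1], design$mz_range[2]),
          intensity = stats::runif(n_noise, design$noise_intensity_range[1],
                                   design$noise_intensity_range[2]))
      }
      ions <- do.call(rbind, ion_list[!vapply(ion_list, is.null, TRUE)])
      if (is.null(ions))
        ions <- data.frame(scan = integer(0), mz = numeric(0),
                           intensity = numeric(0))
      ions <- ions[order(ions$scan, ions$mz), , drop = FALSE]
      rownames(ions) <- NULL
      runs[[s]] <- new_centroid_run(sample_id[s], group[s], scan_rt, ions)
    }
    names(runs) <- sample_id

    truth <- structure(list(catalog = catalog, realized = realized,
                            sample_id = sample_id, group = group,
                            design = design),
                       class = "ground_truth")
    list(runs = runs, truth = truth)
  })
}

#' Construct a centroid run object
#'
#' @param sample_id Sample identifier.
#' @param group Group label, `"C"` or `"T"`.
#' @param scan_rt Strictly increasing scan retention times, minutes.
#' @param ions Data frame with columns `scan` (index into `scan_rt`),
#'   `mz`, `intensity`.
#' @return An object of class `centroid_run`.
#' @export
new_centroid_run <- function(sample_id, group, scan_rt, ions) {
  if (is.unsorted(scan_rt, strictly = TRUE))
    stopf("scan retention times must be strictly increasing (run '%s')",
          sample_id)
  if (nrow(ions) && (any(ions$intensity < 0) || any(!is.finite(ions$mz))))
    stopf("run '%s': ion intensities must be >= 0 and m/z finite", sample_id)
  if (nrow(ions) && (any(ions$scan < 1) || any(ions$scan > length(scan_rt))))
    stopf("run '%s': ion scan index out of range", sample_id)
  structure(list(sample_id = sample_id, group = group,
                 scan_rt = as.numeric(scan_rt), ions = ions),
            class = "centroid_run")
}

#' @export
print.centroid_run <- function(x, ...) {
  cat(sprintf("Centroid LC-MS run '%s' (group %s): %d scans, %d ions, Rt %.3g-%.3g min\n",
              x$sample_id, x$group, length(x$scan_rt), nrow(x$ions),
              min(x$scan_rt), max(x$scan_rt)))
  invisible(x)
}

#' Per-scan view of a centroid run
#'
#' @param run A `centroid_run`.
#' @return A list with one element per scan: `list(rt =, mz =, intensity =)`.
#' @export
run_scans <- function(run) {
  stopifnot(inherits(run, "centroid_run"))
  by_scan <- split(run$ions[c("mz", "intensity")],
                   factor(run$ions$scan, levels = seq_along(run$scan_rt)))
  lapply(seq_along(run$scan_rt), function(i)
    list(rt = run$scan_rt[i], mz = by_scan[[i]]$mz,
         intensity = by_scan[[i]]$intensity))
}
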