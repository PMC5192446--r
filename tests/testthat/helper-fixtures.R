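# Shared fixtures, built lazily and memoized so expensive cohorts are
# generated once per test run.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# A small cohort (short gradient, 25 metabolites) for fast pipeline tests.
small_design <- function(...) {
  args <- list(rt_range = c(1, 4), n_background_metabolites = 20L,
               n_discriminating_metabolites = 5L, seed = 7L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(build_design, args)
}
small_cohort <- function() memo_fixture("small_cohort",
                                        generate_cohort(small_design()))

# The full default cohort: the study conditions (9 C / 15 T, 200
# metabolites, 10 discriminating at fold change 8).
default_cohort <- function() memo_fixture("default_cohort",
                                          generate_cohort(build_design()))

# A noise-free, well-separated cohort for exact recovery checks.
clean_cohort <- function() memo_fixture("clean_cohort", {
  generate_cohort(build_design(
    rt_range = c(1, 6), n_background_metabolites = 30L,
    n_discriminating_metabolites = 5L, noise_ion_density = 0,
    intensity_cv = 0, adduct_probability = 0, mz_jitter_sd = 0.0005,
    base_intensity_meanlog = log(800), base_intensity_sdlog = 0.4,
    seed = 42L))
})

# One centroid run holding given Gaussian peaks on a uniform grid.
gaussian_run <- function(centers_rt, mz, heights, sigma = 0.05,
                         rt_range = c(1, 3), scan_interval = 0.005,
                         sample_id = "G1", group = "C") {
  scan_rt <- seq(rt_range[1], rt_range[2], by = scan_interval)
  ions <- do.call(rbind, lapply(seq_along(centers_rt), function(i) {
    inten <- heights[i] * exp(-(scan_rt - centers_rt[i])^2 / (2 * sigma^2))
    keep <- inten > 1e-6
    data.frame(scan = which(keep), mz = mz[i], intensity = inten[keep])
  }))
  ions <- ions[order(ions$scan, ions$mz), ]
  new_centroid_run(sample_id, group, scan_rt, ions)
}

# Hand-built aligned_features object for threshold/normalization tests.
make_aligned <- function(heights, rt = NULL, mz = NULL,
                         params = processing_params()) {
  n_feat <- ncol(heights)
  if (is.null(rt)) rt <- seq(2, by = 1, length.out = n_feat)
  if (is.null(mz)) mz <- seq(200, by = 50, length.out = n_feat)
  if (is.null(rownames(heights)))
    rownames(heights) <- sprintf("S%02d", seq_len(nrow(heights)))
  features <- data.frame(feature_id = sprintf("%.2f_%.4f", rt, mz),
                         rt = rt, mz = mz, stringsAsFactors = FALSE)
  colnames(heights) <- features$feature_id
  structure(list(features = features, heights = heights,
                 sample_ids = rownames(heights), params = params),
            class = "aligned_features")
}

# Wrap a bare matrix as a feature_table (groups optional).
make_feature_table <- function(values, group = NULL,
                               params = processing_params()) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("f%03d", seq_len(ncol(values)))
  if (is.null(group))
    group <- rep(c("C", "T"), length.out = nrow(values))
  features <- data.frame(feature_id = colnames(values),
                         rt = seq_len(ncol(values)),
                         mz = 100 + 5 * seq_len(ncol(values)),
                         stringsAsFactors = FALSE)
  structure(list(values = values, sample_id = rownames(values),
                 group = group, features = features, params = params),
            class = "feature_table")
}

# Subset a feature table by sample index.
subset_samples <- function(ft, idx) {
  ft$values <- ft$values[idx, , drop = FALSE]
  ft$sample_id <- ft$sample_id[idx]
  ft$group <- ft$group[idx]
  ft
}
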