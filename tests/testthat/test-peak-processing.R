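# Matrix creation: ROI construction, peak detection against closed-form
# oracles, alignment, intensity thresholding and normalization.

test_that("ions within the mass tolerance share an ROI, beyond it they split", {
  scan_rt <- seq(1, 1.05, by = 0.005)
  run_near <- new_centroid_run("a", "C", scan_rt,
                               data.frame(scan = c(1L, 2L),
                                          mz = c(300.0000, 300.0030),
                                          intensity = c(10, 20)))
  rois <- build_rois(run_near, processing_params(mass_tolerance = 0.005,
                                                 rt_range = c(0, 2)))
  expect_length(rois, 1)
  expect_equal(rois[[1]]$n_members, 2L)

  run_far <- new_centroid_run("a", "C", scan_rt,
                              data.frame(scan = c(1L, 2L),
                                         mz = c(300.000, 300.020),
                                         intensity = c(10, 20)))
  rois <- build_rois(run_far, processing_params(mass_tolerance = 0.005,
                                                rt_range = c(0, 2)))
  expect_length(rois, 2)
})

test_that("ROIs partition the in-range ions of a run", {
  run <- small_cohort()$runs[[1]]
  params <- processing_params()
  rois <- build_rois(run, params)
  rt <- run$scan_rt[run$ions$scan]
  in_range <- run$ions$intensity > 0 &
    rt >= params$rt_range[1] & rt <= params$rt_range[2] &
    run$ions$mz >= params$mz_range[1] & run$ions$mz <= params$mz_range[2]
  expect_equal(sum(vapply(rois, `[[`, 0L, "n_members")), sum(in_range))
  for (roi in rois[1:20])
    expect_true(all(abs(roi$member_mz - roi$mz_center) <=
                      params$mass_tolerance + 1e-12))
})

test_that("a clean run yields one ROI per catalog entry with full traces", {
  coh <- clean_cohort()
  rois <- build_rois(coh$runs[[1]], processing_params())
  expect_length(rois, nrow(coh$truth$catalog))
  expect_true(all(vapply(rois, `[[`, 0L, "n_members") >= 5L))
})

test_that("a noiseless Gaussian peak is quantified to its closed form", {
  h <- 1000; sigma <- 0.05; center <- 2
  run <- gaussian_run(center, 300, h, sigma = sigma, rt_range = c(1, 3))
  params <- processing_params(sg_window = 11L, baseline_threshold = 3)
  peaks <- detect_run_peaks(run, params)
  expect_equal(nrow(peaks), 1)
  expect_lt(abs(peaks$rt_apex - center), 0.005 + 1e-9)  # one scan
  expect_equal(peaks$area, h * sigma * sqrt(2 * pi), tolerance = 0.02)
  expect_equal(peaks$height, h, tolerance = 0.02)
  expect_lt(peaks$rt_left_infl, peaks$rt_apex)
  expect_gt(peaks$rt_right_infl, peaks$rt_apex)
})

test_that("a flat EIC contains no peaks", {
  scan_rt <- seq(1, 2, by = 0.005)
  run <- new_centroid_run("a", "C", scan_rt,
                          data.frame(scan = seq_along(scan_rt), mz = 300,
                                     intensity = 50))
  peaks <- detect_run_peaks(run, processing_params(sg_window = 11L,
                                                   baseline_threshold = 3))
  expect_equal(nrow(peaks), 0)
})

test_that("two resolved Gaussians give two peaks in apex order", {
  run <- gaussian_run(c(1.8, 2.3), c(300, 300), c(1000, 600), sigma = 0.05,
                      rt_range = c(1, 3))
  peaks <- detect_run_peaks(run, processing_params(sg_window = 11L,
                                                   baseline_threshold = 3))
  expect_equal(nrow(peaks), 2)
  peaks <- peaks[order(peaks$rt_apex), ]
  expect_lt(abs(peaks$rt_apex[1] - 1.8), 0.01)
  expect_lt(abs(peaks$rt_apex[2] - 2.3), 0.01)
  expect_gt(peaks$height[1], peaks$height[2])
})

test_that("alignment groups within-window peaks and splits beyond-window ones", {
  params <- processing_params()
  same <- data.frame(
    sample_id = c("S1", "S2", "S3"),
    mz = c(300.001, 300.003, 299.998), rt_apex = c(2.00, 2.05, 1.98),
    height = c(100, 120, 90))
  al <- align_peaks(same, params, sample_ids = c("S1", "S2", "S3"))
  expect_equal(nrow(al$features), 1)
  expect_equal(sum(!is.na(al$heights)), 3)

  apart <- data.frame(sample_id = c("S1", "S2"), mz = c(300, 300),
                      rt_apex = c(2.0, 2.5), height = c(100, 100))
  al2 <- align_peaks(apart, params, sample_ids = c("S1", "S2"))
  expect_equal(nrow(al2$features), 2)
})

test_that("a clean cohort recovers the catalog exactly with no missing cells", {
  coh <- clean_cohort()
  ft <- process_cohort(coh$runs, processing_params())
  cat_df <- coh$truth$catalog
  expect_equal(ncol(ft$values), nrow(cat_df))
  expect_equal(sum(is.na(ft$values)), 0)
  # feature coordinates match the truth within (scan_interval, 2 * jitter sd)
  d <- coh$truth$design
  for (i in seq_len(nrow(cat_df))) {
    j <- which.min(abs(ft$features$mz - cat_df$mz_center[i]))
    expect_lt(abs(ft$features$mz[j] - cat_df$mz_center[i]),
              2 * d$mz_jitter_sd)
    expect_lt(abs(ft$features$rt[j] - cat_df$rt_center[i]),
              d$scan_interval + 1e-9)
  }
})

test_that("the intensity threshold keeps features by max height and lowers the per-sample cutoff", {
  params <- processing_params(intensity_threshold = 100,
                              noise_elimination_level = 10)
  al <- make_aligned(matrix(c(120, 40, 8), ncol = 1), params = params)
  out <- apply_intensity_threshold(al, params)
  expect_equal(ncol(out$heights), 1)
  expect_equal(as.numeric(out$heights), c(120, 40, NA))

  al2 <- make_aligned(matrix(c(90, 80), ncol = 1), params = params)
  out2 <- apply_intensity_threshold(al2, params)
  expect_equal(ncol(out2$heights), 0)
})

test_that("raising the intensity threshold prunes features and noise monotonically", {
  coh <- small_cohort()
  ft10 <- process_cohort(coh$runs, processing_params(intensity_threshold = 10))
  ft100 <- process_cohort(coh$runs, processing_params(intensity_threshold = 100))
  expect_lt(ncol(ft100$values), ncol(ft10$values))
  expect_lt(mean(noise_flags(ft100, coh$truth)),
            mean(noise_flags(ft10, coh$truth)))
})

test_that("total-intensity normalization conserves row sums and sample scale", {
  al <- make_aligned(rbind(c(2, 3, 5), c(4, 6, 10)))
  ft <- normalize_total_intensity(al, c("C", "T"))
  expect_equal(as.numeric(ft$values[1, ]), c(2000, 3000, 5000))
  expect_equal(unname(rowSums(ft$values, na.rm = TRUE)), c(10000, 10000),
               tolerance = 1e-6)
  # doubling one sample's raw heights leaves its normalized row unchanged
  al2 <- make_aligned(rbind(c(4, 6, 10), c(4, 6, 10)))
  ft2 <- normalize_total_intensity(al2, c("C", "T"))
  expect_equal(ft2$values[1, ], ft$values[1, ])
  # zero-intensity sample is an error naming the sample
  al3 <- make_aligned(rbind(c(1, 2, 3), c(NA, NA, NA)))
  al3$heights[2, ] <- NA
  expect_error(normalize_total_intensity(al3, c("C", "T")), "S02")
})
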