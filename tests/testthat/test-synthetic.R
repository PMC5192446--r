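# Synthetic cohort generator: design validation, determinism, and the
# statistical calibration of the planted effects.

test_that("default design mirrors the study conditions", {
  d <- build_design()
  expect_identical(d$n_control, 9L)
  expect_identical(d$n_treated, 15L)
  expect_equal(d$rt_range, c(1, 15))
  expect_equal(d$mz_range, c(100, 1000))
  d2 <- build_design(mz_range = c(100, 1000))
  expect_equal(d2$mz_range, c(100, 1000))
})

test_that("invalid designs are rejected with the offending field named", {
  expect_error(build_design(n_control = 2), "n_control")
  expect_error(build_design(fold_changes = -1), "fold_changes")
  expect_error(build_design(rt_range = c(5, 2)), "rt_range")
  expect_error(build_design(intensity_cv = -0.1), "intensity_cv")
  expect_error(build_design(adduct_probability = 1.5), "adduct_probability")
})

test_that("identical designs generate identical cohorts", {
  d <- small_design()
  c1 <- generate_cohort(d)
  c2 <- generate_cohort(d)
  expect_identical(c1$runs, c2$runs)
  expect_identical(c1$truth$realized, c2$truth$realized)
  # and the generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_cohort(d)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("without noise, every ion traces back to its catalog entry", {
  d <- build_design(n_control = 3L, n_treated = 3L, rt_range = c(1, 3),
                    n_background_metabolites = 1L,
                    n_discriminating_metabolites = 0L,
                    noise_ion_density = 0, adduct_probability = 0,
                    seed = 5L)
  coh <- generate_cohort(d)
  cat_entry <- coh$truth$catalog[1, ]
  for (run in coh$runs) {
    ions <- run$ions[run$ions$intensity > 0, ]
    expect_gt(nrow(ions), 0)
    expect_true(all(abs(run$scan_rt[ions$scan] - cat_entry$rt_center) <=
                      4 * d$peak_sigma_rt + 1e-12))
    expect_true(all(abs(ions$mz - cat_entry$mz_center) <=
                      4 * d$mz_jitter_sd + 1e-12))
  }
})

test_that("no-noise cohorts conserve the planted catalog per run", {
  coh <- clean_cohort()
  cat_df <- coh$truth$catalog
  for (run in coh$runs[1:3]) {
    hits <- vapply(seq_len(nrow(cat_df)), function(m) {
      any(abs(run$scan_rt[run$ions$scan] - cat_df$rt_center[m]) <= 0.1 &
            abs(run$ions$mz - cat_df$mz_center[m]) <= 0.01)
    }, TRUE)
    expect_true(all(hits))
  }
})

test_that("group-mean intensity ratios are calibrated to the fold change", {
  # zero biological CV: the ratio is exact
  d0 <- build_design(n_background_metabolites = 2L,
                     n_discriminating_metabolites = 3L, fold_changes = 8,
                     intensity_cv = 0, noise_ion_density = 0,
                     rt_range = c(1, 3), seed = 3L)
  coh0 <- generate_cohort(d0)
  tr <- coh0$truth
  disc <- tr$catalog$is_discriminating & is.na(tr$catalog$adduct_of)
  for (id in tr$catalog$id[disc]) {
    ratio <- mean(tr$realized[id, tr$group == "T"]) /
      mean(tr$realized[id, tr$group == "C"])
    expect_equal(ratio, 8, tolerance = 1e-12)
  }
  # CV 0.1: sample-mean ratio within +/- 2 SE of the lognormal mean ratio
  d1 <- build_design(n_background_metabolites = 2L,
                     n_discriminating_metabolites = 3L, fold_changes = 8,
                     intensity_cv = 0.1, noise_ion_density = 0,
                     rt_range = c(1, 3), seed = 3L)
  tr1 <- generate_cohort(d1)$truth
  for (id in tr1$catalog$id[disc]) {
    ratio <- mean(tr1$realized[id, tr1$group == "T"]) /
      mean(tr1$realized[id, tr1$group == "C"])
    expect_gt(ratio, 6)
    expect_lt(ratio, 10.7)
  }
})

test_that("adduct ions shadow their parent at the Na/H mass shift", {
  d <- build_design(n_background_metabolites = 30L,
                    n_discriminating_metabolites = 0L,
                    adduct_probability = 1, rt_range = c(1, 3),
                    noise_ion_density = 0, seed = 9L)
  tr <- generate_cohort(d)$truth
  adducts <- tr$catalog[!is.na(tr$catalog$adduct_of), ]
  expect_equal(nrow(adducts), 30L)
  parents <- tr$catalog[match(adducts$adduct_of, tr$catalog$id), ]
  expect_equal(adducts$mz_center - parents$mz_center,
               rep(21.9819, nrow(adducts)), tolerance = 1e-9)
  # realized intensities perfectly correlated with the parent
  for (i in seq_len(3)) {
    r <- stats::cor(tr$realized[adducts$id[i], ],
                    tr$realized[adducts$adduct_of[i], ])
    expect_equal(r, 1, tolerance = 1e-12)
  }
})

test_that("centroid run invariants are enforced", {
  expect_error(new_centroid_run("x", "C", c(2, 1, 3),
                                data.frame(scan = 1L, mz = 100,
                                           intensity = 1)),
               "strictly increasing")
  expect_error(new_centroid_run("x", "C", c(1, 2),
                                data.frame(scan = 1L, mz = 100,
                                           intensity = -5)),
               ">= 0")
})
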