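# Feature selection: S-plot coordinates against a brute-force correlation
# oracle, VIP normalization, dot-plot overlap arithmetic, the conjunctive
# rule and its monotonicity, and recovery power versus effect size.

fit_small_model <- function() {
  coh <- small_cohort()
  ft <- process_cohort(coh$runs, processing_params())
  pt <- pretreat(ft, pretreatment_spec(scaling = "pareto"))
  list(coh = coh, ft = ft, pt = pt, model = fit_oplsda(pt))
}

test_that("S-plot coordinates equal the direct covariance/correlation oracle", {
  f <- fit_small_model()
  sp <- splot(f$model)
  X <- f$model$X
  for (k in seq_len(ncol(X))) {
    expect_equal(sp$p1[k], cov(f$model$t, X[, k], use = "pairwise.complete.obs"),
                 tolerance = 1e-10)
    expect_equal(sp$pcorr1[k], cor(f$model$t, X[, k], use = "pairwise.complete.obs"),
                 tolerance = 1e-10)
  }
  expect_true(all(abs(sp$pcorr1) <= 1 + 1e-10, na.rm = TRUE))
})

test_that("a feature proportional to the predictive score has pcorr1 = 1", {
  set.seed(50)
  y <- rep(c("C", "T"), each = 8)
  X <- matrix(rnorm(16 * 10), 16, 10) + outer(as.numeric(y == "T"), rnorm(10))
  m0 <- fit_oplsda(X, y, n_ortho = 0)
  X[, 1] <- 3 * m0$t + 7
  m <- fit_oplsda(X, y, n_ortho = 0)
  sp <- splot(m)
  expect_gte(sp$pcorr1[1], 0.999)
})

test_that("VIP is normalized and uniform under uniform weights", {
  f <- fit_small_model()
  v <- vip(f$model)
  expect_equal(mean(v^2), 1, tolerance = 1e-8)
  expect_equal(sum(v^2), length(v), tolerance = 1e-6)
  vp <- vip(f$model, predictive_only = TRUE)
  expect_equal(mean(vp^2), 1, tolerance = 1e-8)

  # all features identical -> uniform weights -> all VIP exactly 1
  set.seed(51)
  base <- rnorm(12) + 2 * rep(0:1, each = 6)
  Xu <- matrix(rep(base, 6), 12, 6) + 1e-9 * matrix(rnorm(72), 12, 6)
  mu <- fit_oplsda(Xu, rep(c("C", "T"), each = 6), n_ortho = 0)
  expect_equal(unname(vip(mu)), rep(1, 6), tolerance = 1e-3)
})

test_that("group range overlap follows interval arithmetic", {
  vals <- rbind(c(1, 0, 5), c(2, 4, 5), c(3, 2, 5),
                c(10, 2, 5), c(11, 4, 5), c(12, 6, 5))
  ft <- make_feature_table(vals, group = rep(c("C", "T"), each = 3))
  expect_equal(group_overlap(ft, ft$group, "f001"), 0)        # disjoint
  expect_equal(group_overlap(ft, ft$group, "f002"), 2 / 6)    # [0,4] vs [2,6]
  expect_equal(group_overlap(ft, ft$group, "f003"), 1)        # identical
  ft$values[4:6, 1] <- NA
  expect_error(group_overlap(ft, ft$group, "f001"), "non-missing")
})

test_that("selection applies the conjunctive rule and is monotone in the criteria", {
  f <- fit_small_model()
  sel <- select_features(f$model, f$ft)
  ev <- sel$evidence
  expect_identical(sel$selected,
                   ev$feature_id[!is.na(ev$pcorr1) & abs(ev$p1) >= 0.05 &
                                   abs(ev$pcorr1) >= 0.5 & ev$vip > 1])
  # a feature failing pcorr is rejected regardless of VIP
  weak <- ev$feature_id[abs(ev$pcorr1) < 0.5]
  expect_length(intersect(sel$selected, weak), 0)
  # tightening any criterion never adds a feature
  for (crit in list(selection_criteria(p1_min = 0.2),
                    selection_criteria(pcorr_min = 0.8),
                    selection_criteria(vip_min = 2),
                    selection_criteria(require_no_overlap = TRUE))) {
    tighter <- select_features(f$model, f$ft, criteria = crit)
    expect_true(all(tighter$selected %in% sel$selected))
  }
})

test_that("an invalid model triggers a selection warning", {
  f <- fit_small_model()
  fake_val <- list(cv_anova = list(valid = FALSE),
                   permutation = list(valid = TRUE))
  expect_warning(select_features(f$model, f$ft, validation = fake_val),
                 "not be trusted")
})

test_that("recovery power increases with the planted fold change", {
  sens <- vapply(c(2, 8), function(fc) {
    coh <- generate_cohort(small_design(fold_changes = fc, seed = 31L))
    ft <- process_cohort(coh$runs, processing_params())
    pt <- pretreat(ft, pretreatment_spec(scaling = "pareto"))
    sel <- select_features(fit_oplsda(pt), ft)
    evaluate_against_truth(sel, coh$truth)$sensitivity
  }, 0)
  expect_gte(sens[2], sens[1])
  expect_gte(sens[2], 0.8)
})
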