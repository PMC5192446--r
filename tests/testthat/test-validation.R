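# Model diagnostics: Hotelling T2 limit and coverage, DModX normalization
# and planted-outlier detection, CV-ANOVA, permutation test mechanics.

test_that("the Hotelling T2 limit follows the F formula", {
  set.seed(40)
  X <- matrix(rnorm(25 * 12), 25, 12)
  m <- fit_pca(X, ncomp = 2)
  h <- hotelling_t2(m, alpha = 0.05)
  expect_equal(h$limit, 2 * 24 / 23 * qf(0.95, 2, 23), tolerance = 1e-12)
  expect_true(all(h$t2 >= 0))
  # an observation with zero scores sits at T2 = 0 (score-space origin)
  m$scores[1, ] <- 0
  expect_equal(hotelling_t2(m)$t2[[1]], 0)
  expect_error(hotelling_t2(fit_pca(matrix(rnorm(8), 2, 4), ncomp = 2)),
               "N > A")
})

test_that("DModX is zero for exact low-rank data and spots a planted outlier", {
  set.seed(41)
  X <- tcrossprod(matrix(rnorm(20 * 2), 20, 2),
                  matrix(rnorm(50 * 2), 50, 2))
  m <- fit_pca(X, ncomp = 2)
  d <- dmodx(m)
  expect_true(all(d$dmodx < 1e-5))

  # homogeneous residuals + one observation with 10x residual noise
  E <- matrix(rnorm(30 * 120, sd = 0.2), 30, 120)
  E[7, ] <- rnorm(120, sd = 2)
  Xo <- tcrossprod(matrix(rnorm(30 * 2, sd = 4), 30, 2),
                   qr.Q(qr(matrix(rnorm(120 * 2), 120, 2)))) + E
  mo <- fit_pca(Xo, ncomp = 2)
  do <- dmodx(mo)
  expect_identical(which.max(do$dmodx), 7L)
  expect_gt(do$dmodx[7], do$dcrit)
})

test_that("CV-ANOVA degenerates to F = 0, p = 1 when PRESS equals SS", {
  fake <- structure(list(cv = list(press = 4, ss = 4), y = rep(0:1, 6),
                         n_ortho = 0L), class = "oplsda_model")
  res <- cv_anova(fake)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_false(res$valid)
  fake_small <- structure(list(cv = list(press = 1, ss = 4), y = rep(0:1, 1),
                               n_ortho = 2L), class = "oplsda_model")
  expect_error(cv_anova(fake_small), "N >")
})

test_that("CV-ANOVA separates a real effect from permuted labels", {
  coh <- small_cohort()
  ft <- process_cohort(coh$runs, processing_params())
  pt <- pretreat(ft, pretreatment_spec(scaling = "pareto"))
  m <- fit_oplsda(pt)
  expect_lt(cv_anova(m)$p, 0.05)
  set.seed(42)
  p_null <- replicate(5, cv_anova(fit_oplsda(pt, sample(pt$group)))$p)
  expect_gte(mean(p_null > 0.05), 0.8)
})

test_that("the permutation test is deterministic and self-consistent", {
  coh <- small_cohort()
  ft <- process_cohort(coh$runs, processing_params())
  pt <- pretreat(ft, pretreatment_spec(scaling = "pareto"))
  m <- fit_oplsda(pt)
  r1 <- permutation_test(pt, n = 10, seed = 5, true_model = m)
  r2 <- permutation_test(pt, n = 10, seed = 5, true_model = m)
  expect_identical(r1$permutations, r2$permutations)
  expect_equal(nrow(r1$permutations), 10)
  expect_true(all(r1$permutations$correlation >= 0 &
                    r1$permutations$correlation <= 1))
  # refitting under the identity relabeling reproduces the true model
  m_same <- fit_oplsda(pt, pt$group)
  expect_equal(m_same$r2y, m$r2y, tolerance = 1e-8)
  expect_equal(m_same$q2, m$q2, tolerance = 1e-8)
})

test_that("a strong model passes the permutation criterion with negative Q2 intercept", {
  coh <- small_cohort()
  ft <- process_cohort(coh$runs, processing_params())
  pt <- pretreat(ft, pretreatment_spec(scaling = "pareto"))
  m <- fit_oplsda(pt)
  r <- permutation_test(pt, n = 20, seed = 1, true_model = m)
  expect_true(r$valid)
  expect_gt(m$q2, max(r$permutations$q2))
  expect_lt(r$q2_intercept, 0)
})
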