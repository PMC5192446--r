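# NIPALS PCA: SVD equivalence on complete data, missing-value behaviour,
# variance bookkeeping, and element-wise cross-validation with the R1 rule.

test_that("NIPALS equals the truncated SVD on complete data", {
  set.seed(10)
  X <- matrix(rnorm(24 * 50), 24, 50)
  m <- fit_pca(X, ncomp = 5)
  sv <- svd(X, nu = 5, nv = 5)
  for (a in 1:5) {
    t_svd <- sv$u[, a] * sv$d[a]
    sign_flip <- sign(sum(m$scores[, a] * t_svd))
    expect_equal(m$scores[, a], sign_flip * t_svd, tolerance = 1e-6)
    expect_equal(m$loadings[, a], sign_flip * sv$v[, a], tolerance = 1e-6)
  }
  # orthonormal loadings, orthogonal scores
  expect_equal(crossprod(m$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  ct <- crossprod(m$scores)
  expect_lt(max(abs(ct[upper.tri(ct)])) / max(diag(ct)), 1e-6)
  # variance bookkeeping: explained + residual = 1
  expect_equal(sum(m$r2x) + sum(m$E^2) / m$ss_total, 1, tolerance = 1e-8)
  expect_true(all(diff(m$r2x_cum) >= -1e-12))
})

test_that("a rank-1 matrix is recovered exactly", {
  set.seed(11)
  t_true <- rnorm(24)
  p_true <- rnorm(40)
  X <- tcrossprod(t_true, p_true)
  m <- fit_pca(X, ncomp = 1)
  expect_equal(m$r2x[1], 1, tolerance = 1e-10)
  cosine <- abs(sum(m$loadings[, 1] * p_true)) /
    sqrt(sum(p_true^2))
  expect_equal(cosine, 1, tolerance = 1e-8)
})

test_that("missing cells are tolerated: rank-1 recovery with 10% deleted", {
  set.seed(12)
  X <- tcrossprod(rnorm(24) + 2, rlnorm(40))
  X[sample(length(X), round(0.1 * length(X)))] <- NA
  m <- fit_pca(X, ncomp = 1)
  expect_gt(m$r2x[1], 0.99)
})

test_that("element-wise CV retains the planted rank and rejects pure noise", {
  set.seed(13)
  # rank-2 signal with 1% noise -> retain exactly 2
  T2 <- matrix(rnorm(24 * 2), 24, 2) %*% diag(c(8, 4))
  P2 <- qr.Q(qr(matrix(rnorm(40 * 2), 40, 2)))
  X <- tcrossprod(T2, P2) + matrix(rnorm(24 * 40, sd = 0.08), 24, 40)
  cv <- crossvalidate_pca(X, max_components = 5)
  expect_identical(cv$n_retained, 2L)
  expect_true(all(cv$q2[1:2] > 0))
  expect_lte(cv$q2[3], 0)

  # iid Gaussian noise -> at most one marginal component (median over seeds)
  retained <- q2_first <- numeric(20)
  for (s in 1:20) {
    set.seed(100 + s)
    Xn <- matrix(rnorm(24 * 30), 24, 30)
    cvn <- crossvalidate_pca(Xn, max_components = 3)
    retained[s] <- cvn$n_retained
    q2_first[s] <- cvn$q2[1]
  }
  expect_lte(stats::median(retained), 1)
  expect_lte(stats::median(q2_first), 0.05)
})

test_that("CV folds reduce with a warning when N is small", {
  set.seed(14)
  X <- matrix(rnorm(5 * 12), 5, 12)
  expect_warning(cv <- crossvalidate_pca(X, max_components = 2), "folds")
  expect_identical(cv$folds, 5L)
})

test_that("degenerate inputs raise errors", {
  expect_error(fit_pca(matrix(0, 5, 5), ncomp = 1), "no variance")
  expect_error(fit_pca(matrix(rnorm(4), 1, 4), ncomp = 1), "at least 2")
})
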