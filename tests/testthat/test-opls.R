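# OPLS-DA: equivalence to single-component PLS-DA, separation of predictive
# and orthogonal variation, prediction, and the Q2 <= R2Y ordering.

# Independent single-component PLS oracle (complete data, centered y).
pls1_oracle <- function(X, y01) {
  y0 <- y01 - mean(y01)
  w <- as.numeric(crossprod(X, y0))
  w <- w / sqrt(sum(w^2))
  t <- as.numeric(X %*% w)
  q <- sum(t * y0) / sum(t^2)
  list(w = w, t = t, q = q, r2y = 1 - sum((y0 - t * q)^2) / sum(y0^2))
}

test_that("OPLS-DA with zero orthogonal components equals 1-component PLS-DA", {
  set.seed(20)
  y <- rep(c("C", "T"), c(9, 15))
  X <- matrix(rnorm(24 * 30), 24, 30) +
    outer(as.numeric(y == "T"), rnorm(30))
  m <- fit_oplsda(X, y, n_ortho = 0)
  o <- pls1_oracle(X, as.numeric(y == "T"))
  sign_flip <- sign(sum(m$w * o$w))
  expect_equal(m$w, sign_flip * o$w, tolerance = 1e-8)
  expect_equal(m$t, sign_flip * o$t, tolerance = 1e-8)
  expect_equal(m$r2y, o$r2y, tolerance = 1e-8)
})

test_that("the predictive loading finds the class direction; orthogonal variation is absorbed", {
  set.seed(21)
  K <- 40
  v <- rnorm(K); v <- v / sqrt(sum(v^2))        # class direction
  u <- rnorm(K); u <- u - sum(u * v) * v; u <- u / sqrt(sum(u^2))
  y <- rep(c("C", "T"), each = 12)
  class_axis <- outer(ifelse(y == "T", 2, -2), v)
  z <- rnorm(24, sd = 5)                        # strong unrelated variation,
  z <- resid(lm(z ~ y))                         # uncorrelated with the class
  ortho_axis <- outer(z, u)
  X <- class_axis + ortho_axis + matrix(rnorm(24 * K, sd = 0.05), 24, K)
  X <- scale(X, scale = FALSE)[, ]              # models expect centered X
  m <- fit_oplsda(X, y, max_ortho = 3)
  expect_gte(m$n_ortho, 1)
  cosine <- abs(sum(m$p * v)) / sqrt(sum(m$p^2))
  expect_gte(cosine, 0.99)
  # orthogonal weights orthogonal to the predictive weight
  if (m$n_ortho > 0)
    expect_lt(max(abs(crossprod(m$w, m$W_o))), 1e-8)
})

test_that("perfectly separated classes give R2Y near 1", {
  set.seed(22)
  y <- rep(c("C", "T"), c(9, 15))
  X <- outer(as.numeric(y == "T"), rep(1, 10)) * 5 +
    matrix(rnorm(240, sd = 1e-3), 24, 10)
  X <- scale(X, scale = FALSE)[, ]              # models expect centered X
  m <- fit_oplsda(X, y)
  expect_gte(m$r2y, 0.99)
  expect_gte(m$q2, 0.99)
})

test_that("training observations re-predict their own fitted values", {
  coh <- small_cohort()
  ft <- process_cohort(coh$runs, processing_params())
  pt <- pretreat(ft, pretreatment_spec(scaling = "pareto"))
  m <- fit_oplsda(pt)
  pred <- predict(m, pt$values[, !pt$excluded, drop = FALSE])
  expect_equal(pred$t_pred, m$t, tolerance = 1e-8)
  expect_identical(unname(pred$class == "T"), m$y == 1)
  # the overall mean observation predicts the centered-response midpoint
  mean_obs <- matrix(colMeans(pt$values, na.rm = TRUE), 1,
                     dimnames = list(NULL, colnames(pt$values)))
  pm <- predict(m, mean_obs[, !pt$excluded, drop = FALSE])
  expect_equal(pm$y_pred, 0, tolerance = 1e-8)
})

test_that("prediction rejects observations with mismatched features", {
  set.seed(23)
  y <- rep(c("C", "T"), each = 6)
  X <- matrix(rnorm(12 * 8), 12, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  m <- fit_oplsda(X, y)
  bad <- X[, 1:5]
  expect_error(predict(m, bad), "f6")
})

test_that("Q2 never exceeds R2Y across random two-class problems", {
  for (s in 1:8) {
    set.seed(30 + s)
    y <- rep(c("C", "T"), c(9, 15))
    effect <- runif(1, 0, 2)
    X <- matrix(rnorm(24 * 25), 24, 25) +
      outer(as.numeric(y == "T"), rnorm(25, sd = effect))
    m <- fit_oplsda(X, y)
    expect_lte(m$q2, m$r2y + 1e-10)
  }
})

test_that("class constraints are enforced", {
  X <- matrix(rnorm(40), 8, 5)
  expect_error(fit_oplsda(X, rep("A", 8)), "2 classes")
  expect_error(fit_oplsda(X, c(rep("A", 7), "B")), "at least 2 samples")
})
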