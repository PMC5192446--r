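# Pre-treatment: missing-value filtering, transformation formulas, and the
# post-scaling moments of center/UV/Pareto scaling.

test_that("features beyond the missing threshold are dropped, others kept", {
  set.seed(1)
  x <- matrix(rlnorm(24 * 5, 5), 24, 5)
  x[1:13, 3] <- NA  # 54% missing
  ft <- make_feature_table(x)
  out <- filter_missing(ft, pretreatment_spec())
  expect_equal(ncol(out$values), 4)
  expect_identical(attr(out, "dropped_features"), "f003")

  # fully observed table unchanged; threshold 1 drops nothing
  full <- make_feature_table(matrix(rlnorm(20, 5), 4, 5))
  expect_equal(filter_missing(full, pretreatment_spec())$values, full$values)
  out2 <- filter_missing(ft, pretreatment_spec(missing_threshold = 1))
  expect_equal(ncol(out2$values), 5)

  allna <- make_feature_table(matrix(NA_real_, 4, 2))
  expect_error(filter_missing(allna, pretreatment_spec()), "all features")
})

test_that("log and power transformations follow the stated formulas", {
  ft <- make_feature_table(matrix(c(100, 3, 0, 10), 2, 2))
  lg <- transform_values(ft, pretreatment_spec(transform = "log"))
  expect_equal(lg$values[1, 1], 2)           # log10(1*100 + 0)
  expect_true(is.na(lg$values[1, 2]))        # log10(0) -> missing
  expect_equal(attr(lg, "n_new_missing"), 1L)

  pw <- transform_values(ft, pretreatment_spec(transform = "power"))
  expect_equal(pw$values[2, 1], 9)           # (1*3 + 0)^2
  expect_equal(pw$values[1, 1], 10000)

  ident <- transform_values(ft, pretreatment_spec(transform = "none"))
  expect_equal(ident$values, ft$values)
})

test_that("scaling produces the specified column moments", {
  x <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(5, 5, 5),
             d = rlnorm(3, 3))
  ft <- make_feature_table(x, group = c("C", "C", "T"))

  ctr <- scale_values(ft, pretreatment_spec(scaling = "center"))
  expect_equal(unname(ctr$values[, 1]), c(-1, 0, 1))
  expect_equal(unname(colMeans(ctr$values)), rep(0, 4), tolerance = 1e-10)

  uv <- scale_values(ft, pretreatment_spec(scaling = "uv"))
  expect_equal(stats::var(uv$values[, 2]), 1, tolerance = 1e-10)
  expect_true(uv$excluded[3])                # zero variance -> weight 0
  expect_equal(unname(uv$weight[3]), 0)

  par <- scale_values(ft, pretreatment_spec(scaling = "pareto"))
  expect_equal(stats::var(par$values[, 4]), stats::sd(x[, 4]),
               tolerance = 1e-8)             # var((x-m)/sqrt(s)) = s

  none <- scale_values(ft, pretreatment_spec(scaling = "none"))
  expect_equal(none$values, ft$values)

  short <- make_feature_table(matrix(c(1, NA, NA, 2, 3, 4), 3, 2))
  expect_error(scale_values(short, pretreatment_spec(scaling = "uv")),
               "fewer than 2")
})

test_that("stored parameters reproduce the raw matrix exactly", {
  set.seed(2)
  x <- matrix(rlnorm(24 * 10, 5, 1), 24, 10)
  x[sample(length(x), 20)] <- NA
  ft <- make_feature_table(x)
  for (sc in c("none", "center", "uv", "pareto")) {
    pt <- scale_values(ft, pretreatment_spec(scaling = sc))
    expect_equal(back_project(pt), ft$values, tolerance = 1e-10)
  }
  # apply_pretreatment on the training rows reproduces the scaled matrix
  pt <- pretreat(ft, pretreatment_spec(transform = "log", scaling = "pareto"))
  re <- apply_pretreatment(pt, ft)
  expect_equal(re, pt$values, tolerance = 1e-12)
})

test_that("transform happens before scaling", {
  set.seed(3)
  x <- matrix(rlnorm(30, 4), 6, 5)
  ft <- make_feature_table(x)
  pt <- pretreat(ft, pretreatment_spec(transform = "log", scaling = "uv"))
  manual <- scale(log10(x))  # center + unit variance of the log values
  expect_equal(unname(pt$values), unname(manual[, ]), tolerance = 1e-10)
})
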