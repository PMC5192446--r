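# Model diagnostics: Hotelling's T2 normality area, DModX moderate-outlier
# detection against Dcrit, CV-ANOVA on cross-validated predictive
# residuals, and the response permutation test with R2/Q2 intercepts.

model_scores <- function(model) {
  if (inherits(model, "pca_model")) return(model$scores)
  if (inherits(model, "oplsda_model"))
    return(cbind(model$t, if (model$n_ortho) model$T_o))
  stopf("unsupported model class '%s'", class(model)[1])
}

#' Hotelling's T-squared per observation with its F-based limit
#'
#' `T2_i = sum_a t_ia^2 / s_a^2` with `s_a^2` the (n-1) score variance;
#' the limit at level `alpha` is `A (N-1) / (N-A) * F_(1-alpha)(A, N-A)`.
#' Observations above the limit fall outside the normality area and are
#' flagged strong outliers.
#'
#' @param model A `pca_model` or `oplsda_model`.
#' @param alpha Significance level (default 0.05, i.e. a 95\% normality
#'   area).
#' @return List with per-observation `t2`, the `limit`, and logical
#'   `strong_outlier`.
#' @export
hotelling_t2 <- function(model, alpha = 0.05) {
  Tm <- model_scores(model)
  N <- nrow(Tm); A <- ncol(Tm)
  if (N <= A) stopf("Hotelling T2 needs N > A (N = %d, A = %d)", N, A)
  s2 <- apply(Tm, 2, stats::var)
  t2 <- rowSums(sweep(Tm^2, 2, s2, "/"))
  limit <- A * (N - 1) / (N - A) * stats::qf(1 - alpha, A, N - A)
  list(t2 = t2, limit = limit, strong_outlier = t2 > limit, alpha = alpha)
}

#' Normalized distance to the model in X-space (DModX) with Dcrit
#'
#' `s_i = sqrt(sum_k e_ik^2 / (K - A))` and
#' `s_0 = sqrt(sum e^2 / ((N - A - 1)(K - A)))`; `DModX_i = s_i / s_0` in
#' normalized units.  `Dcrit = sqrt(F_(1-alpha)(K - A, (N - A - 1)(K - A)))`.
#' Observations above Dcrit are flagged moderate outliers.  With missing
#' cells, each observation's residual sum is rescaled by `K / K_i(observed)`
#' before applying the complete-data degrees of freedom.
#'
#' @param model A `pca_model` or `oplsda_model` with residuals.
#' @param alpha Significance level (default 0.05).
#' @return List with per-observation `dmodx`, `dcrit`, and logical
#'   `moderate_outlier`.
#' @export
dmodx <- function(model, alpha = 0.05) {
  E <- model$E
  A <- if (inherits(model, "oplsda_model")) 1L + model$n_ortho else model$ncomp
  N <- nrow(E); K <- ncol(E)
  if (K <= A) stopf("DModX needs K > A (K = %d, A = %d)", K, A)
  k_obs <- rowSums(!is.na(E))
  row_ss <- rowSums(E^2, na.rm = TRUE) * (K / pmax(k_obs, 1))
  s_i <- sqrt(row_ss / (K - A))
  df0 <- (N - A - 1) * (K - A)
  s_0 <- sqrt(sum(row_ss) / df0)
  # numerically exact fit: all residuals are floating-point dust
  negligible <- sum(row_ss) <= 1e-12 * (model$ss_total %||% 1)
  dm <- if (s_0 > 0 && !negligible) s_i / s_0 else rep(0, N)
  dcrit <- sqrt(stats::qf(1 - alpha, K - A, df0))
  list(dmodx = dm, dcrit = dcrit, moderate_outlier = dm > dcrit,
       s0 = s_0, alpha = alpha)
}

#' CV-ANOVA: F-test on cross-validated predictive residuals
#'
#' Compares the cross-validated PRESS of the fitted OPLS-DA model against
#' the total corrected response variation:
#' `F = ((SS_y - PRESS)/df1) / (PRESS/df2)` with
#' `df1 = (predictive + orthogonal components) + 1` model parameters and
#' `df2 = N - df1`.  The model is conventionally called reliable when
#' `p < 0.05`.
#'
#' @param model An `oplsda_model` (carries its CV record).
#' @return List with `F`, `df1`, `df2`, `p`, and `valid` (p < 0.05).
#' @export
cv_anova <- function(model) {
  stopifnot(inherits(model, "oplsda_model"))
  press <- model$cv$press
  ss_y <- model$cv$ss
  N <- length(model$y)
  df1 <- 1L + model$n_ortho + 1L
  df2 <- N - df1
  if (df2 <= 0) stopf("CV-ANOVA needs N > number of model parameters")
  f <- ((ss_y - press) / df1) / (press / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(F = f, df1 = df1, df2 = df2, p = p, valid = is.finite(p) && p < 0.05)
}

#' Response permutation test for an OPLS-DA model
#'
#' The class vector is shuffled `n` times (class sizes preserved), a full
#' OPLS-DA (same orthogonal-component policy) is refit to each permuted
#' response, and (label correlation, R2Y, Q2) are recorded.  Regression
#' lines through the permuted points plus the true model (at correlation 1)
#' give the R2 and Q2 intercepts at correlation 0.  The model passes when
#' the true R2Y and Q2 exceed every permuted value.
#'
#' @param pt A `pretreated_table` (or matrix) the model was fit on.
#' @param y True group labels.
#' @param n Number of permutations (default 50).
#' @param seed RNG seed for the shuffle sequence.
#' @param max_ortho,folds,correction_factor Passed to [fit_oplsda()].
#' @param include_true Include the true model as the correlation-1 point of
#'   the intercept regression (the usual convention); set FALSE to regress
#'   through permuted points only.
#' @param true_model Optionally, the already-fitted true model (refit when
#'   NULL).
#' @return A `permutation_test` result: data frame `permutations`
#'   (`correlation`, `r2y`, `q2`), the true `r2y`/`q2`, the two intercepts,
#'   and `valid`.
#' @export
permutation_test <- function(pt, y = NULL, n = 50L, seed = 1L,
                             max_ortho = 5L, folds = 7L,
                             correction_factor = 3,
                             include_true = TRUE, true_model = NULL) {
  stopifnot(n >= 1)
  if (is.null(y)) y <- pt$group
  if (is.null(true_model))
    true_model <- fit_oplsda(pt, y, max_ortho = max_ortho, folds = folds,
                             correction_factor = correction_factor)
  y_num <- as.numeric(factor(y, levels = sort(unique(y)))) - 1

  perms <- with_seed(seed, replicate(n, sample(y), simplify = FALSE))
  rec <- vapply(perms, function(yp) {
    m <- fit_oplsda(pt, yp, max_ortho = max_ortho, folds = folds,
                    correction_factor = correction_factor)
    yp_num <- as.numeric(factor(yp, levels = sort(unique(y)))) - 1
    c(correlation = abs(stats::cor(yp_num, y_num)), r2y = m$r2y, q2 = m$q2)
  }, c(correlation = 0, r2y = 0, q2 = 0))
  perm_df <- as.data.frame(t(rec))

  xs <- perm_df$correlation
  r2s <- perm_df$r2y
  q2s <- perm_df$q2
  if (include_true) {
    xs <- c(xs, 1)
    r2s <- c(r2s, true_model$r2y)
    q2s <- c(q2s, true_model$q2)
  }
  r2_int <- unname(stats::coef(stats::lm(r2s ~ xs))[1])
  q2_int <- unname(stats::coef(stats::lm(q2s ~ xs))[1])

  structure(list(
    permutations = perm_df,
    r2y = true_model$r2y, q2 = true_model$q2,
    r2_intercept = r2_int, q2_intercept = q2_int,
    valid = all(true_model$r2y > perm_df$r2y) &&
      all(true_model$q2 > perm_df$q2),
    n = n, seed = seed
  ), class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    paste0("Response permutation test (n = %d)\n",
           "  true R2Y = %.3f, Q2 = %.3f; intercepts R2 = (0.0, %.3f), Q2 = (0.0, %.3f)\n",
           "  %s\n"),
    x$n, x$r2y, x$q2, x$r2_intercept, x$q2_intercept,
    if (x$valid) "true model exceeds all permuted models"
    else "NOT valid: some permuted model matches or beats the true model"))
  invisible(x)
}

#' Assemble the full validation report for a model pair
#'
#' @param pca_model A fitted `pca_model` (may be NULL).
#' @param oplsda_model A fitted `oplsda_model`.
#' @param pt The `pretreated_table` both models were fit on.
#' @param alpha Outlier significance level.
#' @param n_perm Permutations for the response permutation test.
#' @param seed Seed for the permutation shuffles.
#' @param max_ortho Orthogonal-component cap used in permuted refits.
#' @return A `validation_report` list: `hotelling`, `dmodx`, `cv_anova`,
#'   `permutation`.
#' @export
validate_models <- function(pca_model, oplsda_model, pt, alpha = 0.05,
                            n_perm = 50L, seed = 1L, max_ortho = 5L) {
  structure(list(
    hotelling = if (!is.null(pca_model)) hotelling_t2(pca_model, alpha),
    dmodx = if (!is.null(pca_model)) dmodx(pca_model, alpha),
    cv_anova = cv_anova(oplsda_model),
    permutation = permutation_test(pt, oplsda_model$group, n = n_perm,
                                   seed = seed, max_ortho = max_ortho,
                                   true_model = oplsda_model)
  ), class = "validation_report")
}
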