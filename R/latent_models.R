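# Latent-variable models: missing-value-aware NIPALS PCA with element-wise
# seven-fold cross-validation and R1 component retention, and OPLS-DA
# (one predictive component plus CV-chosen orthogonal components).
#
# Missing cells are handled NIPALS-style: every score/loading regression
# runs over non-missing cells only, with the per-element denominator scale
# N/(non-missing count) capped at a correction factor (default 3.0) so that
# sparsely observed rows or columns cannot acquire extrapolated leverage.

# Loading-type regression: for each column k, sum_i(x_ik t_i)/sum_i(t_i^2)
# over non-missing cells, denominator floored at sum(t^2)/cap.
nipals_loading <- function(X0, M, t, cap = 3) {
  num <- as.numeric(crossprod(X0, t))
  den <- as.numeric(crossprod(M, t^2))
  if (is.finite(cap)) den <- pmax(den, sum(t^2) / cap)
  den[den == 0] <- 1
  num / den
}

# Score-type regression: for each row i, sum_k(x_ik p_k)/sum_k(p_k^2).
nipals_score <- function(X0, M, p, cap = 3) {
  num <- as.numeric(X0 %*% p)
  den <- as.numeric(M %*% p^2)
  if (is.finite(cap)) den <- pmax(den, sum(p^2) / cap)
  den[den == 0] <- 1
  num / den
}

# Strip excluded columns and split a pretreated matrix into the zero-filled
# matrix and its presence mask.
model_matrix_parts <- function(pt) {
  X <- pt$values[, !pt$excluded, drop = FALSE]
  M <- !is.na(X) * 1
  X0 <- X
  X0[is.na(X0)] <- 0
  list(X = X, X0 = X0, M = M)
}

#' Fit a PCA model by missing-value-aware NIPALS
#'
#' Components are extracted sequentially; after each, the matrix is
#' deflated on its non-missing cells.  On complete data the result matches
#' a truncated SVD up to column sign.
#'
#' @param pt A `pretreated_table` (or a bare numeric matrix, possibly with
#'   NAs, for programmatic use).
#' @param ncomp Number of components to extract.
#' @param correction_factor Missing-value leverage cap (default 3.0); set
#'   `Inf` to disable.
#' @param tol Relative score-change convergence tolerance.
#' @param max_iter Maximum NIPALS iterations per component; exceeding it is
#'   an error.  The default 5000 accommodates the slow power-iteration
#'   convergence of nearly degenerate noise components.
#' @return A `pca_model`: scores `T` (N x A), orthonormal loadings `P`
#'   (K x A), per-component and cumulative `r2x`, residual matrix `E`
#'   (NA at missing cells), score variances, and the training data.
#' @export
fit_pca <- function(pt, ncomp = 2, correction_factor = 3,
                    tol = 1e-10, max_iter = 5000L) {
  if (is.matrix(pt))
    pt <- list(values = pt, excluded = rep(FALSE, ncol(pt)),
               sample_id = rownames(pt) %||% as.character(seq_len(nrow(pt))),
               group = NULL, spec = NULL)
  mp <- model_matrix_parts(pt)
  X0 <- mp$X0; M <- mp$M
  N <- nrow(X0); K <- ncol(X0)
  if (N < 2 || K < 2) stopf("need at least 2 samples and 2 usable features")
  ss_total <- sum(X0^2)
  if (ss_total == 0) stopf("matrix has no variance")

  Tm <- matrix(0, N, ncomp)
  P <- matrix(0, K, ncomp)
  r2x <- numeric(ncomp)
  a_done <- 0L
  for (a in seq_len(ncomp)) {
    ss_before <- sum(X0^2)
    if (ss_before / ss_total < 1e-12) break
    t <- X0[, which.max(colSums(X0^2))]
    if (sum(t^2) == 0) break
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      p <- nipals_loading(X0, M, t, correction_factor)
      p <- p / sqrt(sum(p^2))
      t_new <- nipals_score(X0, M, p, correction_factor)
      delta <- sqrt(sum((t_new - t)^2)) / sqrt(sum(t_new^2))
      t <- t_new
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      stopf("NIPALS did not converge for component %d within %d iterations",
            a, max_iter)
    X0 <- X0 - tcrossprod(t, p) * M
    Tm[, a] <- t
    P[, a] <- p
    r2x[a] <- (ss_before - sum(X0^2)) / ss_total
    a_done <- a
  }
  if (a_done == 0L) stopf("no component could be extracted")
  Tm <- Tm[, seq_len(a_done), drop = FALSE]
  P <- P[, seq_len(a_done), drop = FALSE]
  r2x <- r2x[seq_len(a_done)]
  E <- mp$X - tcrossprod(Tm, P)  # NA where X is missing
  structure(list(
    ncomp = a_done, scores = Tm, loadings = P,
    r2x = r2x, r2x_cum = cumsum(r2x),
    score_var = apply(Tm, 2, stats::var),
    E = E, X = mp$X, ss_total = ss_total,
    correction_factor = correction_factor,
    sample_id = pt$sample_id, group = pt$group, spec = pt$spec
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  q2 <- attr(x, "q2_cum")
  cat(sprintf("PCA (NIPALS): %d components, N = %d, K = %d\n  R2X(cum) = %.3f%s\n",
              x$ncomp, nrow(x$scores), nrow(x$loadings),
              x$r2x_cum[x$ncomp],
              if (!is.null(q2)) sprintf(", Q2(cum) = %.3f", q2) else ""))
  invisible(x)
}

#' Cross-validate a NIPALS PCA by element-wise deletion
#'
#' Cells are assigned to seven groups by `(row + col) mod folds`; for each
#' group, a model fit without those cells predicts them.  Per component,
#' `Q2_a = 1 - PRESS_a / SS_(a-1)` with `SS_(a-1)` the residual sum of
#' squares of the full-data model after `a - 1` components.  Components are
#' retained while cumulative Q2 increases (the R1 rule).
#'
#' @param pt A `pretreated_table` or numeric matrix.
#' @param max_components Largest number of components to evaluate.
#' @param folds Number of deletion groups (reduced to N with a warning when
#'   N < folds).
#' @param correction_factor Missing-value leverage cap.
#' @return A `pca_cv` result: per-component `press`, `ss`, `q2`, `q2_cum`,
#'   and `n_retained`.
#' @export
crossvalidate_pca <- function(pt, max_components = 10, folds = 7L,
                              correction_factor = 3) {
  if (is.matrix(pt))
    pt <- list(values = pt, excluded = rep(FALSE, ncol(pt)),
               sample_id = rownames(pt) %||% as.character(seq_len(nrow(pt))),
               group = NULL, spec = NULL)
  mp <- model_matrix_parts(pt)
  X <- mp$X
  N <- nrow(X); K <- ncol(X)
  if (N < folds) {
    warnf("only %d samples: reducing CV folds from %d to %d", N, folds, N)
    folds <- N
  }
  max_components <- min(max_components, N - 1L, K)

  # residual SS after each component of the full-data model
  full <- fit_pca(pt, ncomp = max_components,
                  correction_factor = correction_factor)
  max_components <- full$ncomp
  ss <- c(full$ss_total, full$ss_total * (1 - full$r2x_cum))
  if (ss[1] == 0) stopf("degenerate matrix: zero total sum of squares")

  cell_group <- (outer(seq_len(N) - 1L, seq_len(K) - 1L, "+")) %% folds
  press <- matrix(0, folds, max_components)
  for (g in seq_len(folds) - 1L) {
    del <- cell_group == g & !is.na(X)
    Xcv <- X
    Xcv[del] <- NA
    M <- !is.na(Xcv) * 1
    X0 <- Xcv
    X0[is.na(X0)] <- 0
    xhat <- matrix(0, N, K)
    for (a in seq_len(max_components)) {
      t <- X0[, which.max(colSums(X0^2))]
      if (sum(t^2) == 0) { press[g + 1L, a:max_components] <- NA; break }
      for (it in seq_len(5000L)) {
        p <- nipals_loading(X0, M, t, correction_factor)
        p <- p / sqrt(sum(p^2))
        t_new <- nipals_score(X0, M, p, correction_factor)
        delta <- sqrt(sum((t_new - t)^2)) / sqrt(sum(t_new^2))
        t <- t_new
        if (delta < 1e-10) break
      }
      X0 <- X0 - tcrossprod(t, p) * M
      xhat <- xhat + tcrossprod(t, p)
      press[g + 1L, a] <- sum((X[del] - xhat[del])^2)
    }
  }
  press_a <- colSums(press)
  q2 <- 1 - press_a / ss[seq_len(max_components)]
  ratio <- press_a / ss[seq_len(max_components)]
  q2_cum <- 1 - cumprod(ratio)
  n_retained <- 0L
  for (a in seq_len(max_components)) {
    if (is.finite(q2[a]) && q2[a] > 0) n_retained <- a else break
  }
  structure(list(folds = folds, press = press_a,
                 ss = ss[seq_len(max_components)], q2 = q2, q2_cum = q2_cum,
                 n_retained = n_retained),
            class = "pca_cv")
}

#' @export
print.pca_cv <- function(x, ...) {
  cat(sprintf("PCA cross-validation (%d-fold, element-wise): %d component(s) retained\n",
              x$folds, x$n_retained))
  df <- data.frame(component = seq_along(x$q2), Q2 = round(x$q2, 4),
                   Q2_cum = round(x$q2_cum, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

# --- OPLS-DA ---------------------------------------------------------------

encode_y <- function(group) {
  lev <- sort(unique(group))
  if (length(lev) != 2) stopf("OPLS-DA requires exactly 2 classes, got %d",
                              length(lev))
  if (any(table(group) < 2)) stopf("each class needs at least 2 samples")
  y <- as.numeric(group == lev[2])  # first level -> 0, second -> 1
  list(y = y, levels = lev)
}

# Deterministic class-stratified round-robin fold assignment after sorting
# sample ids.
stratified_folds <- function(sample_id, group, folds) {
  fold <- integer(length(sample_id))
  for (g in unique(group)) {
    idx <- which(group == g)
    idx <- idx[order(sample_id[idx])]
    fold[idx] <- (seq_along(idx) - 1L) %% folds + 1L
  }
  fold
}

# Core OPLS fit on a zero-filled matrix + mask with a fixed number of
# orthogonal components.  y0 must be centered.
opls_core <- function(X0, M, y0, n_ortho, cap = 3) {
  K <- ncol(X0)
  w <- nipals_loading(X0, M, y0, cap)
  wn <- sqrt(sum(w^2))
  if (wn == 0) stopf("X carries no covariance with the class vector")
  w <- w / wn
  W_o <- P_o <- matrix(0, K, 0)
  T_o <- matrix(0, nrow(X0), 0)
  ss_ortho <- numeric(0)
  Xc <- X0
  j <- 0L
  while (j < n_ortho) {
    t <- nipals_score(Xc, M, w, cap)
    p <- nipals_loading(Xc, M, t, cap)
    w_o <- p - as.numeric(crossprod(w, p)) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) break
    w_o <- w_o / nw
    t_o <- nipals_score(Xc, M, w_o, cap)
    p_o <- nipals_loading(Xc, M, t_o, cap)
    recon <- tcrossprod(t_o, p_o) * M
    Xc <- Xc - recon
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
    ss_ortho <- c(ss_ortho, sum(recon^2))
    j <- j + 1L
  }
  t <- nipals_score(Xc, M, w, cap)
  p <- nipals_loading(Xc, M, t, cap)
  q <- sum(t * y0) / sum(t^2)
  list(w = w, t = t, p = p, q = q, W_o = W_o, P_o = P_o, T_o = T_o,
       n_ortho = ncol(W_o), ss_ortho = ss_ortho,
       ss_pred = sum((tcrossprod(t, p) * M)^2))
}

# Project rows of a (zero-filled, masked) matrix through a fitted core:
# strip orthogonal variation, then compute the predictive score.
opls_project <- function(core, X0, M, cap = 3) {
  Xc <- X0
  for (j in seq_len(core$n_ortho)) {
    t_o <- nipals_score(Xc, M, core$W_o[, j], cap)
    Xc <- Xc - tcrossprod(t_o, core$P_o[, j]) * M
  }
  nipals_score(Xc, M, core$w, cap)
}

# Seven-fold observation-wise CV of an OPLS model with n_ortho orthogonal
# components; returns Q2 and the per-sample cross-validated prediction.
opls_cv_q2 <- function(X0, M, y, fold, n_ortho, cap = 3) {
  yhat <- rep(NA_real_, length(y))
  for (g in sort(unique(fold))) {
    tr <- fold != g
    ytr <- y[tr]
    ybar <- mean(ytr)
    core <- opls_core(X0[tr, , drop = FALSE], M[tr, , drop = FALSE],
                      ytr - ybar, n_ortho, cap)
    t_new <- opls_project(core, X0[!tr, , drop = FALSE],
                          M[!tr, , drop = FALSE], cap)
    yhat[!tr] <- t_new * core$q + ybar
  }
  ss <- sum((y - mean(y))^2)
  list(q2 = 1 - sum((y - yhat)^2) / ss, yhat = yhat, press = sum((y - yhat)^2),
       ss = ss)
}

#' Fit an OPLS-DA model
#'
#' Splits X-variation into one predictive component (correlated with the
#' class) and orthogonal components (uncorrelated with it).  The class is
#' encoded 0/1 and centered.  Orthogonal components are added while the
#' seven-fold observation-wise cross-validated Q2 increases, up to
#' `max_ortho`; folds are class-stratified and assigned round-robin after
#' sorting sample ids, so the fit is deterministic.
#'
#' @param pt A `pretreated_table`, or a numeric matrix together with `y`.
#' @param y Group labels (2 classes); defaults to the table's groups.
#' @param n_ortho `"auto"` (CV-chosen) or a fixed count.
#' @param max_ortho Cap on orthogonal components.
#' @param folds CV folds (default 7).
#' @param correction_factor Missing-value leverage cap.
#' @return An `oplsda_model` with the predictive part (`w`, `t`, `p`, `q`),
#'   orthogonal parts (`W_o`, `T_o`, `P_o`), `r2y`, `q2`, `r2x_pred`,
#'   `r2x_ortho`, the cross-validation record (`cv`), and the training
#'   matrix.
#' @export
fit_oplsda <- function(pt, y = NULL, n_ortho = "auto", max_ortho = 5L,
                       folds = 7L, correction_factor = 3) {
  if (is.matrix(pt))
    pt <- list(values = pt, excluded = rep(FALSE, ncol(pt)),
               sample_id = rownames(pt) %||% as.character(seq_len(nrow(pt))),
               group = y, spec = NULL)
  if (is.null(y)) y <- pt$group
  enc <- encode_y(y)
  mp <- model_matrix_parts(pt)
  X0 <- mp$X0; M <- mp$M
  N <- nrow(X0)
  folds <- min(folds, N)
  fold <- stratified_folds(pt$sample_id, y, folds)
  y0 <- enc$y - mean(enc$y)
  ss_total <- sum(X0^2)

  if (identical(n_ortho, "auto")) {
    q2_path <- numeric(0)
    best <- opls_cv_q2(X0, M, enc$y, fold, 0L, correction_factor)
    q2_path <- best$q2
    chosen <- 0L
    j <- 1L
    while (j <= max_ortho) {
      cand <- opls_cv_q2(X0, M, enc$y, fold, j, correction_factor)
      q2_path <- c(q2_path, cand$q2)
      if (cand$q2 > best$q2) {
        best <- cand
        chosen <- j
        j <- j + 1L
      } else break
    }
    n_ortho <- chosen
    cv <- best
  } else {
    n_ortho <- as.integer(n_ortho)
    cv <- opls_cv_q2(X0, M, enc$y, fold, n_ortho, correction_factor)
    q2_path <- cv$q2
  }

  core <- opls_core(X0, M, y0, n_ortho, correction_factor)
  yfit <- core$t * core$q
  r2y <- 1 - sum((y0 - yfit)^2) / sum(y0^2)
  E <- mp$X - tcrossprod(core$t, core$p) -
    (if (core$n_ortho) tcrossprod(core$T_o, core$P_o) else 0)
  fitted_class_means <- tapply(yfit, y, mean)

  structure(list(
    w = core$w, t = core$t, p = core$p, q = core$q,
    W_o = core$W_o, T_o = core$T_o, P_o = core$P_o,
    n_ortho = core$n_ortho,
    r2y = r2y, q2 = cv$q2,
    r2x_pred = core$ss_pred / ss_total,
    r2x_ortho = sum(core$ss_ortho) / ss_total,
    r2x_ortho_each = core$ss_ortho / ss_total,
    r2x_cum = (core$ss_pred + sum(core$ss_ortho)) / ss_total,
    levels = enc$levels, y = enc$y, y0 = y0,
    fitted_class_means = fitted_class_means,
    cv = list(folds = folds, fold = fold, q2_path = q2_path,
              press = cv$press, ss = cv$ss, yhat = cv$yhat),
    E = E, X = mp$X, ss_total = ss_total,
    score_var = c(stats::var(core$t),
                  if (core$n_ortho) apply(core$T_o, 2, stats::var)),
    correction_factor = correction_factor,
    sample_id = pt$sample_id, group = y,
    pretreatment = pt[c("center", "weight", "excluded", "spec")],
    feature_names = colnames(mp$X)
  ), class = "oplsda_model")
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat(sprintf(
    paste0("OPLS-DA: 1 predictive + %d orthogonal component(s), classes %s/%s\n",
           "  R2X(cum) = %.3f (pred %.3f, ortho %.3f), R2Y(cum) = %.3f, Q2(cum) = %.3f\n"),
    x$n_ortho, x$levels[1], x$levels[2],
    x$r2x_cum, x$r2x_pred, x$r2x_ortho, x$r2y, x$q2))
  invisible(x)
}

#' Predict class membership for new observations
#'
#' Orthogonal variation is stripped from each new observation, the
#' predictive score is computed (missing-aware), and the class is the
#' nearest of the two fitted class means on the predicted response.
#'
#' @param object An `oplsda_model`.
#' @param newdata Matrix of pretreated observations with the model's
#'   feature columns (use [apply_pretreatment()] with the training
#'   pretreatment first when starting from raw intensities).
#' @param ... Unused.
#' @return Data frame with predictive score `t_pred`, predicted centered
#'   response `y_pred`, and `class`.
#' @export
predict.oplsda_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && !is.null(object$feature_names)) {
    missing_cols <- setdiff(object$feature_names, colnames(newdata))
    if (length(missing_cols))
      stopf("newdata lacks model feature(s): %s",
            paste(utils::head(missing_cols, 5), collapse = ", "))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  } else if (ncol(newdata) != length(object$w)) {
    stopf("newdata has %d columns; model expects %d", ncol(newdata),
          length(object$w))
  }
  M <- !is.na(newdata) * 1
  X0 <- newdata
  X0[is.na(X0)] <- 0
  core <- object[c("w", "W_o", "P_o", "n_ortho")]
  t_pred <- opls_project(core, X0, M, object$correction_factor)
  y_pred <- t_pred * object$q
  cm <- object$fitted_class_means
  class <- names(cm)[apply(abs(outer(y_pred, cm, "-")), 1, which.min)]
  data.frame(t_pred = t_pred, y_pred = y_pred, class = class,
             stringsAsFactors = FALSE)
}
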