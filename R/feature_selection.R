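# Statistical selection of discriminating variables from an OPLS-DA model:
# S-plot coordinates (covariance p1 vs correlation p(corr)1 against the
# predictive score), variable importance in projection (VIP), and a
# dot-plot group-overlap check on the normalized intensities.

#' S-plot coordinates of every feature
#'
#' For each feature k of the pretreated matrix,
#' `p1_k = cov(t, x_k)` (modeled covariation; sample covariance over
#' non-missing cells) and `pcorr1_k = cor(t, x_k)` (modeled correlation,
#' the reliability axis).  Zero-variance features get `pcorr1 = NA`.
#'
#' @param model A fitted `oplsda_model`.
#' @return Data frame `feature_id, p1, pcorr1`.
#' @export
splot <- function(model) {
  stopifnot(inherits(model, "oplsda_model"))
  X <- model$X
  t <- model$t
  p1 <- apply(X, 2, function(x) stats::cov(t, x, use = "pairwise.complete.obs"))
  pcorr1 <- suppressWarnings(
    apply(X, 2, function(x) stats::cor(t, x, use = "pairwise.complete.obs")))
  data.frame(feature_id = colnames(X) %||% as.character(seq_along(p1)),
             p1 = p1, pcorr1 = pcorr1, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Variable importance in projection (VIP)
#'
#' Combined over the predictive and orthogonal components:
#' `VIP_k = sqrt(K * sum_a SS_a (w_ak/|w_a|)^2 / sum_a SS_a)`, where `SS_a`
#' is the y-variance explained by the predictive component and the
#' X-variance explained by each orthogonal component.  By construction
#' `mean(VIP^2) = 1`.  Set `predictive_only = TRUE` for the
#' predictive-component-only variant.
#'
#' @param model A fitted `oplsda_model`.
#' @param predictive_only Use only the predictive component.
#' @return Named numeric vector of VIP scores.
#' @export
vip <- function(model, predictive_only = FALSE) {
  stopifnot(inherits(model, "oplsda_model"))
  K <- length(model$w)
  # dimensionless variance shares: explained y-fraction for the predictive
  # component, explained X-fractions for the orthogonal ones
  W <- matrix(model$w, ncol = 1)
  ss <- model$r2y
  if (!predictive_only && model$n_ortho > 0) {
    W <- cbind(W, model$W_o)
    ss <- c(ss, model$r2x_ortho_each)
  }
  Wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  v <- sqrt(K * as.numeric(Wn^2 %*% ss) / sum(ss))
  stats::setNames(v, model$feature_names)
}

#' Group range-overlap fraction of one feature (dot-plot surrogate)
#'
#' The dot-plot "no overlap between groups" check reduced to a number:
#' the length of the intersection of the two groups' [min, max] intensity
#' ranges divided by the length of their union range.  0 means disjoint
#' groups (a very strong discriminating variable), 1 identical ranges.
#'
#' @param table A `feature_table` (normalized intensities).
#' @param y Group labels.
#' @param feature_id Feature column to assess.
#' @return Overlap fraction in [0, 1].
#' @export
group_overlap <- function(table, y, feature_id) {
  x <- table$values[, feature_id]
  lev <- sort(unique(y))
  stopifnot(length(lev) == 2)
  a <- x[y == lev[1]]; b <- x[y == lev[2]]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    stopf("feature '%s': a group has no non-missing values", feature_id)
  inter <- min(max(a), max(b)) - max(min(a), min(b))
  uni <- max(max(a), max(b)) - min(min(a), min(b))
  if (uni <= 0) return(1)  # both groups constant and equal
  max(0, inter) / uni
}

#' Feature-selection criteria
#'
#' @param p1_min Covariance cutoff, `|p1| >= p1_min` (default 0.05; applies
#'   to the covariance definition of the p1 axis).
#' @param pcorr_min Reliability cutoff, `|pcorr1| >= pcorr_min`
#'   (default 0.5).
#' @param vip_min VIP cutoff, `vip > vip_min` (default 1.0).
#' @param require_no_overlap Require a zero dot-plot group overlap.
#' @export
selection_criteria <- function(p1_min = 0.05, pcorr_min = 0.5,
                               vip_min = 1.0, require_no_overlap = FALSE) {
  structure(list(p1_min = p1_min, pcorr_min = pcorr_min, vip_min = vip_min,
                 require_no_overlap = require_no_overlap),
            class = "selection_criteria")
}

#' Select discriminating features from a validated OPLS-DA model
#'
#' Conjunctive rule: `|p1| >= p1_min` and `|pcorr1| >= pcorr_min` and
#' `vip > vip_min`, optionally also a zero group overlap.  A warning is
#' emitted when the model failed CV-ANOVA or the permutation criterion:
#' selections from such a model should not be trusted.
#'
#' @param model A fitted `oplsda_model`.
#' @param table The `feature_table` of normalized intensities (for the
#'   dot-plot overlap).
#' @param y Group labels (defaults to the table's groups).
#' @param criteria A [selection_criteria()].
#' @param validation Optional `validation_report` used for the validity
#'   warning and flags.
#' @return A `feature_selection` result: `evidence` data frame
#'   (`feature_id, rt, mz, p1, pcorr1, vip, overlap, selected`),
#'   `selected` ids, and validity flags.
#' @export
select_features <- function(model, table, y = NULL,
                            criteria = selection_criteria(),
                            validation = NULL) {
  if (is.null(y)) y <- table$group
  sp <- splot(model)
  v <- vip(model)
  idx <- match(sp$feature_id, table$features$feature_id)
  overlap <- vapply(sp$feature_id, function(f)
    if (f %in% colnames(table$values)) group_overlap(table, y, f)
    else NA_real_, 0)
  selected <- !is.na(sp$pcorr1) &
    abs(sp$p1) >= criteria$p1_min &
    abs(sp$pcorr1) >= criteria$pcorr_min &
    v > criteria$vip_min
  if (criteria$require_no_overlap)
    selected <- selected & !is.na(overlap) & overlap == 0

  cv_ok <- perm_ok <- NA
  if (!is.null(validation)) {
    cv_ok <- validation$cv_anova$valid
    perm_ok <- validation$permutation$valid
    if (!isTRUE(cv_ok) || !isTRUE(perm_ok))
      warnf("model failed %s: selected features should not be trusted",
            paste(c(if (!isTRUE(cv_ok)) "CV-ANOVA",
                    if (!isTRUE(perm_ok)) "the permutation test"),
                  collapse = " and "))
  }

  evidence <- data.frame(
    feature_id = sp$feature_id,
    rt = table$features$rt[idx], mz = table$features$mz[idx],
    p1 = sp$p1, pcorr1 = sp$pcorr1, vip = unname(v), overlap = overlap,
    selected = selected, stringsAsFactors = FALSE)
  structure(list(evidence = evidence,
                 selected = evidence$feature_id[selected],
                 criteria = criteria,
                 cv_anova_valid = cv_ok, permutation_valid = perm_ok),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("Feature selection: %d of %d features selected (|p1| >= %g, |p(corr)1| >= %g, VIP > %g%s)\n",
              length(x$selected), nrow(x$evidence), x$criteria$p1_min,
              x$criteria$pcorr_min, x$criteria$vip_min,
              if (x$criteria$require_no_overlap) ", no group overlap" else ""))
  if (!is.na(x$cv_anova_valid) &&
      (!isTRUE(x$cv_anova_valid) || !isTRUE(x$permutation_valid)))
    cat("  WARNING: model failed validation; selection untrusted\n")
  invisible(x)
}

#' Write a selection result to CSV with provenance header comments
#'
#' @param selection A `feature_selection`.
#' @param file Output path.
#' @param provenance Named list echoed as `# key: value` comment lines.
#' @export
write_selection <- function(selection, file, provenance = list()) {
  hdr <- c(sprintf("# criteria: |p1|>=%g |pcorr1|>=%g vip>%g no_overlap=%s",
                   selection$criteria$p1_min, selection$criteria$pcorr_min,
                   selection$criteria$vip_min,
                   selection$criteria$require_no_overlap),
           vapply(names(provenance), function(k)
             sprintf("# %s: %s", k, provenance[[k]]), ""))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(selection$evidence, con, row.names = FALSE)
  invisible(file)
}
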