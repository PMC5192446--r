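# Data pre-treatment: missing-value filtering, log/power transformation,
# and column-wise centering / unit-variance / Pareto scaling.
#
# Convention: transform first, then scale; scaling statistics are computed
# on the transformed values.  Log of a non-positive argument becomes a
# missing cell (the downstream NIPALS is missing-aware), with the count
# recorded, rather than an error or a pseudo-count.

#' Pre-treatment specification
#'
#' @param transform `"none"`, `"log"` (y = log10(C1 x + C2)) or `"power"`
#'   (y = (C1 x + C2)^C3).
#' @param C1,C2,C3 Transformation constants (defaults 1, 0, 2).
#' @param scaling `"none"`, `"center"` (x - mean), `"uv"` ((x - mean)/sd) or
#'   `"pareto"` ((x - mean)/sqrt(sd)); sd is the sample (n-1) standard
#'   deviation.
#' @param missing_threshold Maximum tolerated missing fraction per feature
#'   and per sample, in (0, 1]; default 0.5.
#' @return An object of class `pretreatment_spec`.
#' @export
pretreatment_spec <- function(transform = c("none", "log", "power"),
                              C1 = 1, C2 = 0, C3 = 2,
                              scaling = c("none", "center", "uv", "pareto"),
                              missing_threshold = 0.5) {
  transform <- match.arg(transform)
  scaling <- match.arg(scaling)
  if (missing_threshold <= 0 || missing_threshold > 1)
    stopf("missing_threshold must be in (0, 1]")
  structure(list(transform = transform, C1 = C1, C2 = C2, C3 = C3,
                 scaling = scaling, missing_threshold = missing_threshold),
            class = "pretreatment_spec")
}

#' Label for a pre-treatment combination, e.g. "Pareto/Log"
#' @param spec A `pretreatment_spec`.
#' @export
pretreatment_label <- function(spec) {
  sc <- c(none = "None", center = "Center", uv = "UV", pareto = "Pareto")
  tr <- c(none = "None", log = "Log", power = "Power")
  paste(sc[spec$scaling], tr[spec$transform], sep = "/")
}

#' Drop features, then samples, exceeding the missing-value threshold
#'
#' @param table A `feature_table`.
#' @param spec A `pretreatment_spec`.
#' @return The filtered `feature_table`, with attributes
#'   `dropped_features` and `dropped_samples`.
#' @export
filter_missing <- function(table, spec = pretreatment_spec()) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$values
  thr <- spec$missing_threshold
  feat_keep <- colMeans(is.na(x)) <= thr
  if (!any(feat_keep))
    stopf("all features exceed the %.0f%% missing-value threshold", 100 * thr)
  x <- x[, feat_keep, drop = FALSE]
  samp_keep <- rowMeans(is.na(x)) <= thr
  dropped_features <- colnames(table$values)[!feat_keep]
  dropped_samples <- table$sample_id[!samp_keep]
  table$values <- x[samp_keep, , drop = FALSE]
  table$sample_id <- table$sample_id[samp_keep]
  table$group <- table$group[samp_keep]
  table$features <- table$features[feat_keep, , drop = FALSE]
  attr(table, "dropped_features") <- dropped_features
  attr(table, "dropped_samples") <- dropped_samples
  table
}

#' Apply the cell-wise transformation
#'
#' @param table A `feature_table` (or any object with a `values` matrix).
#' @param spec A `pretreatment_spec`.
#' @return The table with transformed values; the number of cells newly
#'   made missing by an undefined log is recorded in attribute
#'   `n_new_missing`.
#' @export
transform_values <- function(table, spec) {
  x <- table$values
  n_new <- 0L
  if (spec$transform == "log") {
    arg <- spec$C1 * x + spec$C2
    bad <- !is.na(arg) & arg <= 0
    n_new <- sum(bad)
    arg[bad] <- NA_real_
    x <- log10(arg)
  } else if (spec$transform == "power") {
    x <- (spec$C1 * x + spec$C2)^spec$C3
  }
  table$values <- x
  attr(table, "n_new_missing") <- n_new
  table
}

#' Scale columns and package the pretreated matrix
#'
#' Column statistics are computed over non-missing cells of the
#' (already transformed) matrix.  Zero-variance columns receive weight 0
#' and are excluded from modeling (recorded in `excluded`).
#'
#' @param table A transformed `feature_table`.
#' @param spec A `pretreatment_spec`.
#' @return A `pretreated_table`: `values` (scaled matrix), `center` and
#'   `weight` per column (scaled = (x - center) * weight), `excluded`
#'   logical, plus sample/feature metadata and the spec.
#' @export
scale_values <- function(table, spec) {
  x <- table$values
  n_obs <- colSums(!is.na(x))
  if (any(n_obs < 2))
    stopf("feature '%s' has fewer than 2 non-missing values",
          colnames(x)[which(n_obs < 2)[1]])
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
  center <- switch(spec$scaling,
                   none = rep(0, ncol(x)),
                   center = mu, uv = mu, pareto = mu)
  weight <- switch(spec$scaling,
                   none = rep(1, ncol(x)),
                   center = rep(1, ncol(x)),
                   uv = ifelse(sdv > 0, 1 / sdv, 0),
                   pareto = ifelse(sdv > 0, 1 / sqrt(sdv), 0))
  excluded <- sdv == 0 & spec$scaling %in% c("uv", "pareto")
  scaled <- sweep(sweep(x, 2, center, "-"), 2, weight, "*")
  structure(list(values = scaled, center = center, weight = weight,
                 excluded = excluded, sample_id = table$sample_id,
                 group = table$group, features = table$features,
                 spec = spec, params = table$params),
            class = "pretreated_table")
}

#' Full pre-treatment: filter, transform, scale
#'
#' @param table A `feature_table`.
#' @param spec A `pretreatment_spec`.
#' @return A `pretreated_table`.
#' @export
pretreat <- function(table, spec = pretreatment_spec()) {
  table <- filter_missing(table, spec)
  table <- transform_values(table, spec)
  scale_values(table, spec)
}

#' Back-project a pretreated matrix to the transformed scale
#'
#' Inverts the scaling using the stored per-column center and weight;
#' weight-0 (excluded) columns are returned as their stored center.
#'
#' @param pt A `pretreated_table`.
#' @return Matrix on the transformed (pre-scaling) scale.
#' @export
back_project <- function(pt) {
  stopifnot(inherits(pt, "pretreated_table"))
  w <- ifelse(pt$weight == 0, 1, pt$weight)
  sweep(sweep(pt$values, 2, w, "/"), 2, pt$center, "+")
}

#' Pre-treat new observations with a fitted table's stored parameters
#'
#' Applies the same transformation, then the stored per-column center and
#' weight, to new observations (columns matched by feature id).
#'
#' @param pt The training `pretreated_table`.
#' @param table A `feature_table` of new observations sharing the training
#'   features.
#' @return Scaled matrix for the new observations.
#' @export
apply_pretreatment <- function(pt, table) {
  idx <- match(colnames(pt$values), colnames(table$values))
  if (anyNA(idx))
    stopf("new observations lack %d training feature(s), e.g. '%s'",
          sum(is.na(idx)), colnames(pt$values)[which(is.na(idx))[1]])
  tbl <- list(values = table$values[, idx, drop = FALSE])
  x <- transform_values(tbl, pt$spec)$values
  sweep(sweep(x, 2, pt$center, "-"), 2, pt$weight, "*")
}

#' @export
print.pretreated_table <- function(x, ...) {
  cat(sprintf("Pretreated table (%s): %d samples x %d features (%d excluded), %.1f%% missing\n",
              pretreatment_label(x$spec), nrow(x$values), ncol(x$values),
              sum(x$excluded), 100 * mean(is.na(x$values))))
  invisible(x)
}
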