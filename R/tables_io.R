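# Table and model serialization: feature-table CSV with a JSON provenance
# sidecar, pretreated-table CSV with stored scaling parameters, and model
# JSON export.

params_to_list <- function(params) {
  lapply(unclass(params), function(x) x)
}

#' Write a feature table as CSV with a provenance sidecar
#'
#' Rows are samples (first columns `sample_id`, `group`), remaining columns
#' are feature ids; missing cells are empty.  The processing parameters and
#' the feature (Rt, m/z) metadata go to `<file>.json`.
#'
#' @param table A `feature_table`.
#' @param file Output CSV path.
#' @return Invisibly, the CSV path.
#' @export
write_feature_table <- function(table, file) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(sample_id = table$sample_id, group = table$group,
                   as.data.frame(table$values, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(params = params_to_list(table$params), features = table$features),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param file CSV path (expects the `.json` sidecar next to it).
#' @return A `feature_table`.
#' @export
read_feature_table <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(values) <- df$sample_id
  params <- do.call(processing_params, meta$params[
    setdiff(names(meta$params), character(0))])
  structure(list(values = values, sample_id = df$sample_id,
                 group = df$group,
                 features = as.data.frame(meta$features,
                                          stringsAsFactors = FALSE),
                 params = params),
            class = "feature_table")
}

#' Write a pretreated table as CSV with its scaling parameters
#'
#' The sidecar JSON records the pre-treatment spec and the per-column
#' center/weight so the matrix can be reproduced from raw values and new
#' observations scaled identically.
#'
#' @param pt A `pretreated_table`.
#' @param file Output CSV path.
#' @return Invisibly, the CSV path.
#' @export
write_pretreated <- function(pt, file) {
  stopifnot(inherits(pt, "pretreated_table"))
  df <- data.frame(sample_id = pt$sample_id, group = pt$group,
                   as.data.frame(pt$values, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(spec = unclass(pt$spec),
         center = as.list(stats::setNames(pt$center, colnames(pt$values))),
         weight = as.list(stats::setNames(pt$weight, colnames(pt$values))),
         excluded = colnames(pt$values)[pt$excluded]),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Serialize a fitted model to JSON
#'
#' Scores, loadings, weights, per-component statistics and (for OPLS-DA)
#' the pre-treatment parameters carried by the model.
#'
#' @param model A `pca_model` or `oplsda_model`.
#' @param file Output JSON path.
#' @return Invisibly, the path.
#' @export
write_model_json <- function(model, file) {
  obj <- if (inherits(model, "pca_model")) {
    list(type = "pca", ncomp = model$ncomp,
         scores = as.data.frame(model$scores),
         loadings = as.data.frame(model$loadings),
         r2x = model$r2x, r2x_cum = model$r2x_cum,
         q2_cum = attr(model, "q2_cum"),
         score_var = model$score_var, sample_id = model$sample_id)
  } else if (inherits(model, "oplsda_model")) {
    list(type = "oplsda", n_ortho = model$n_ortho,
         w = model$w, t = model$t, p = model$p, q = model$q,
         W_o = as.data.frame(model$W_o), T_o = as.data.frame(model$T_o),
         P_o = as.data.frame(model$P_o),
         r2x_cum = model$r2x_cum, r2x_pred = model$r2x_pred,
         r2x_ortho = model$r2x_ortho, r2y = model$r2y, q2 = model$q2,
         levels = model$levels, sample_id = model$sample_id,
         feature_names = model$feature_names,
         pretreatment = list(
           spec = if (!is.null(model$pretreatment$spec))
             unclass(model$pretreatment$spec),
           center = model$pretreatment$center,
           weight = model$pretreatment$weight))
  } else stopf("unsupported model class '%s'", class(model)[1])
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
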