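# Orchestration of the sensitivity experiment: run the full pipeline over
# a grid of pre-processing parameter sets ("Methods": mass tolerance x
# intensity threshold) and pre-treatment combinations (scaling x
# transformation), compare the selected feature sets (Venn/Jaccard), and
# score recovery against the synthetic ground truth.

#' The four canonical pre-processing Methods
#'
#' Mass tolerance 0.005/0.01 Da crossed with intensity threshold 10/100
#' counts.
#'
#' @param ... Overrides passed to every [processing_params()] call.
#' @return Named list of `processing_params` (Method1..Method4).
#' @export
standard_methods <- function(...) {
  grid <- list(Method1 = c(0.005, 10), Method2 = c(0.005, 100),
               Method3 = c(0.01, 10), Method4 = c(0.01, 100))
  lapply(grid, function(g)
    processing_params(mass_tolerance = g[1], intensity_threshold = g[2], ...))
}

#' The eight canonical pre-treatment combinations
#'
#' None/None, Center/None, UV/None, Pareto/None, UV/Log, Pareto/Log,
#' UV/Power, Pareto/Power.
#'
#' @return Named list of `pretreatment_spec`s.
#' @export
standard_pretreatments <- function() {
  rows <- list(c("none", "none"), c("center", "none"), c("uv", "none"),
               c("pareto", "none"), c("uv", "log"), c("pareto", "log"),
               c("uv", "power"), c("pareto", "power"))
  out <- lapply(rows, function(r)
    pretreatment_spec(transform = r[2], scaling = r[1]))
  names(out) <- vapply(out, pretreatment_label, "")
  out
}

#' Run the full pipeline for one Method / pre-treatment cell
#'
#' Matrix creation, pre-treatment, PCA with CV-chosen component count,
#' OPLS-DA, the validation battery, and feature selection, in order.
#'
#' @param runs List of `centroid_run`s (or an already-computed
#'   `feature_table` to skip matrix creation).
#' @param processing A `processing_params`.
#' @param pretreatment A `pretreatment_spec`.
#' @param truth Optional `ground_truth` for noise flags and recovery.
#' @param criteria A [selection_criteria()]; the pipeline default includes
#'   the dot-plot no-overlap confirmation of each S-plot/VIP candidate.
#' @param label Method label for reporting.
#' @param n_perm Permutations in the validation battery.
#' @param seed Seed for the permutation shuffles.
#' @param max_pc,max_ortho Component caps.
#' @return A `method_result`: the feature-table stats, fitted models, the
#'   validation report, the selection, and (with truth) recovery metrics.
#' @export
run_method <- function(runs, processing = processing_params(),
                       pretreatment = pretreatment_spec(scaling = "pareto"),
                       truth = NULL,
                       criteria = selection_criteria(require_no_overlap = TRUE),
                       label = NULL, n_perm = 50L, seed = 1L,
                       max_pc = 10L, max_ortho = 5L) {
  stage <- "matrix creation"
  result <- tryCatch({
    ft <- if (inherits(runs, "feature_table")) runs
          else process_cohort(runs, processing)
    nf <- if (!is.null(truth)) noise_flags(ft, truth) else NULL
    table_stats <- list(
      n_features = ncol(ft$values),
      missing_fraction = mean(is.na(ft$values)),
      noise_fraction = if (!is.null(nf)) mean(nf) else NA_real_)

    stage <- "pre-treatment"
    pt <- pretreat(ft, pretreatment)

    stage <- "PCA"
    cv <- crossvalidate_pca(pt, max_components = max_pc)
    pca <- fit_pca(pt, ncomp = max(cv$n_retained, 1L))
    attr(pca, "q2_cum") <- if (cv$n_retained >= 1)
      cv$q2_cum[cv$n_retained] else cv$q2_cum[1]

    stage <- "OPLS-DA"
    opls <- fit_oplsda(pt, max_ortho = max_ortho)

    stage <- "validation"
    val <- validate_models(pca, opls, pt, n_perm = n_perm, seed = seed,
                           max_ortho = max_ortho)

    stage <- "feature selection"
    sel <- suppressWarnings(
      select_features(opls, ft, criteria = criteria, validation = val))

    recovery <- if (!is.null(truth)) evaluate_against_truth(sel, truth)

    structure(list(
      label = label %||% sprintf("tol=%g/thr=%g/%s",
                                 processing$mass_tolerance,
                                 processing$intensity_threshold,
                                 pretreatment_label(pretreatment)),
      processing = ft$params, pretreatment = pretreatment,
      table_stats = table_stats,
      pca = list(n_pc = pca$ncomp, r2x_cum = pca$r2x_cum[pca$ncomp],
                 q2_cum = attr(pca, "q2_cum")),
      opls = list(r2x_cum = opls$r2x_cum, r2y_cum = opls$r2y,
                  q2_cum = opls$q2, n_ortho = opls$n_ortho),
      validation = val, selection = sel, recovery = recovery,
      models = list(pca = pca, opls = opls, pt = pt), feature_table = ft
    ), class = "method_result")
  }, error = function(e) {
    stopf("[%s | %s] %s", label %||% "method", stage, conditionMessage(e))
  })
  result
}

#' @export
print.method_result <- function(x, ...) {
  cat(sprintf(
    paste0("Method result '%s'\n",
           "  features: %d (%.0f%% missing, noise fraction %s)\n",
           "  PCA: %d PC, R2X(cum) = %.3f, Q2(cum) = %.3f\n",
           "  OPLS-DA: R2X(cum) = %.3f, R2Y(cum) = %.3f, Q2(cum) = %.3f; CV-ANOVA p = %.3g\n",
           "  permutation intercepts: R2 = (0.0, %.3f), Q2 = (0.0, %.3f); %s\n",
           "  selected features: %d%s\n"),
    x$label, x$table_stats$n_features, 100 * x$table_stats$missing_fraction,
    if (is.na(x$table_stats$noise_fraction)) "n/a"
    else sprintf("%.2f", x$table_stats$noise_fraction),
    x$pca$n_pc, x$pca$r2x_cum, x$pca$q2_cum,
    x$opls$r2x_cum, x$opls$r2y_cum, x$opls$q2_cum, x$validation$cv_anova$p,
    x$validation$permutation$r2_intercept,
    x$validation$permutation$q2_intercept,
    if (x$validation$permutation$valid) "valid" else "INVALID",
    length(x$selection$selected),
    if (!is.null(x$recovery))
      sprintf(" (sensitivity %.2f, FDF %s)", x$recovery$sensitivity,
              if (is.na(x$recovery$false_discovery_fraction)) "n/a"
              else sprintf("%.2f", x$recovery$false_discovery_fraction))
    else ""))
  invisible(x)
}

#' Compare selected feature sets across methods
#'
#' Feature ids from different pipeline runs are matched by (Rt, m/z)
#' proximity within the alignment windows (methods differ in mass
#' tolerance, so exact id match is insufficient): selected features are
#' pooled and clustered greedily into a matched universe, then Jaccard
#' similarities and the full Venn region decomposition are computed.
#'
#' @param selections Named list of `feature_selection` results (>= 2), each
#'   carrying rt/mz evidence.
#' @param align_mz_window,align_rt_window Matching windows.
#' @return A `method_comparison`: `membership` (universe x methods logical
#'   matrix), `jaccard` matrix, and `venn` region counts.
#' @export
compare_methods <- function(selections, align_mz_window = 0.05,
                            align_rt_window = 0.20) {
  stopifnot(length(selections) >= 2)
  if (is.null(names(selections)))
    names(selections) <- paste0("method", seq_along(selections))
  sel_df <- do.call(rbind, lapply(names(selections), function(nm) {
    ev <- selections[[nm]]$evidence
    ev <- ev[ev$selected, c("feature_id", "rt", "mz"), drop = FALSE]
    if (nrow(ev)) cbind(method = nm, ev, stringsAsFactors = FALSE)
  }))
  methods <- names(selections)
  if (is.null(sel_df) || nrow(sel_df) == 0) {
    membership <- matrix(FALSE, 0, length(methods),
                         dimnames = list(NULL, methods))
  } else {
    # greedy clustering into matched universe entries (nearest first)
    ord <- order(sel_df$mz, sel_df$rt)
    sel_df <- sel_df[ord, , drop = FALSE]
    n <- nrow(sel_df)
    u_rt <- u_mz <- numeric(0)
    u_members <- list()
    assign_to <- integer(n)
    for (i in seq_len(n)) {
      hit <- 0L
      if (length(u_mz)) {
        dmz <- abs(u_mz - sel_df$mz[i])
        drt <- abs(u_rt - sel_df$rt[i])
        ok <- dmz <= align_mz_window & drt <= align_rt_window
        if (any(ok)) {
          d <- (dmz[ok] / align_mz_window)^2 + (drt[ok] / align_rt_window)^2
          hit <- which(ok)[which.min(d)]
        }
      }
      if (hit == 0L) {
        u_mz <- c(u_mz, sel_df$mz[i])
        u_rt <- c(u_rt, sel_df$rt[i])
        u_members <- c(u_members, list(integer(0)))
        hit <- length(u_mz)
      }
      assign_to[i] <- hit
      u_members[[hit]] <- c(u_members[[hit]], i)
    }
    membership <- matrix(FALSE, length(u_mz), length(methods),
                         dimnames = list(
                           sprintf("%.2f_%.4f", u_rt, u_mz), methods))
    for (i in seq_len(n))
      membership[assign_to[i], sel_df$method[i]] <- TRUE
  }

  m <- ncol(membership)
  jaccard <- matrix(1, m, m, dimnames = list(methods, methods))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    a <- membership[, i]; b <- membership[, j]
    u <- sum(a | b)
    jaccard[i, j] <- if (u == 0) 1 else sum(a & b) / u
  }

  venn <- if (nrow(membership)) {
    key <- apply(membership, 1, function(r)
      paste(methods[r], collapse = "&"))
    table(key)
  } else table(character(0))

  structure(list(membership = membership, jaccard = jaccard,
                 venn = venn, methods = methods),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Method comparison over %d methods; %d matched features\n",
              length(x$methods), nrow(x$membership)))
  core <- sum(rowSums(x$membership) == length(x$methods))
  uniq <- sum(rowSums(x$membership) == 1)
  cat(sprintf("  common core: %d; method-unique: %d\n", core, uniq))
  cat("  Jaccard:\n")
  print(round(x$jaccard, 3))
  invisible(x)
}

#' Score a selection against the synthetic ground truth
#'
#' Selected features are matched to catalog entries within the (Rt, m/z)
#' windows; an adduct match is credited to its parent metabolite.
#' Sensitivity = recovered discriminating metabolites / planted;
#' false-discovery fraction = selected features matching no discriminating
#' entry / selected (NA when nothing is selected).
#'
#' @param selection A `feature_selection`.
#' @param truth A `ground_truth`.
#' @param align_mz_window,align_rt_window Matching windows.
#' @return List with `sensitivity`, `false_discovery_fraction`,
#'   `recovered` (metabolite ids) and `false_positives` (feature ids).
#' @export
evaluate_against_truth <- function(selection, truth,
                                   align_mz_window = 0.05,
                                   align_rt_window = 0.20) {
  cat_df <- truth$catalog
  parent_id <- ifelse(is.na(cat_df$adduct_of), cat_df$id, cat_df$adduct_of)
  parent_disc <- cat_df$is_discriminating[match(parent_id, cat_df$id)]
  planted <- cat_df$id[cat_df$is_discriminating & is.na(cat_df$adduct_of)]

  ev <- selection$evidence[selection$evidence$selected, , drop = FALSE]
  if (nrow(ev) == 0)
    return(list(sensitivity = 0, false_discovery_fraction = NA_real_,
                recovered = character(0), false_positives = character(0)))
  match_ids <- vapply(seq_len(nrow(ev)), function(i) {
    dmz <- abs(cat_df$mz_center - ev$mz[i])
    drt <- abs(cat_df$rt_center - ev$rt[i])
    ok <- dmz <= align_mz_window & drt <= align_rt_window
    if (!any(ok)) return(NA_character_)
    d <- (dmz[ok] / align_mz_window)^2 + (drt[ok] / align_rt_window)^2
    cat_df$id[ok][which.min(d)]
  }, "")
  matched_parent <- parent_id[match(match_ids, cat_df$id)]
  is_disc_hit <- !is.na(match_ids) &
    parent_disc[match(match_ids, cat_df$id)]
  recovered <- unique(matched_parent[is_disc_hit])
  list(
    sensitivity = if (length(planted)) length(recovered) / length(planted)
                  else NA_real_,
    false_discovery_fraction = sum(!is_disc_hit) / nrow(ev),
    recovered = recovered,
    false_positives = ev$feature_id[!is_disc_hit])
}

#' Run the full sensitivity experiment
#'
#' Executes the pipeline over the four pre-processing Methods (under one
#' reference pre-treatment) and the configured pre-treatment grid (under
#' Method-1 processing, whose feature table is computed once and reused),
#' then compares the selected feature sets of each grid.  A failing grid
#' cell is recorded, not fatal.
#'
#' @param runs List of `centroid_run`s.
#' @param truth Optional `ground_truth`.
#' @param methods Named list of `processing_params`
#'   (default [standard_methods()]).
#' @param pretreatments Named list of `pretreatment_spec`s
#'   (default [standard_pretreatments()]).
#' @param reference_pretreatment Pre-treatment used for the Methods grid
#'   (default Pareto, no transformation).
#' @param criteria A [selection_criteria()].
#' @param n_perm,seed,max_pc,max_ortho Passed to [run_method()].
#' @return An `experiment_report`: `method_results`,
#'   `pretreatment_results`, `method_comparison`,
#'   `pretreatment_comparison`, `failures`.
#' @export
run_experiment <- function(runs, truth = NULL,
                           methods = standard_methods(),
                           pretreatments = standard_pretreatments(),
                           reference_pretreatment =
                             pretreatment_spec(scaling = "pareto"),
                           criteria = selection_criteria(require_no_overlap = TRUE),
                           n_perm = 50L, seed = 1L,
                           max_pc = 10L, max_ortho = 5L) {
  failures <- list()
  safe_run <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      failures[[label]] <<- conditionMessage(e)
      NULL
    })
  }

  method_results <- list()
  method1_ft <- NULL
  for (nm in names(methods)) {
    method_results[[nm]] <- safe_run(nm, run_method(
      runs, methods[[nm]], reference_pretreatment, truth = truth,
      criteria = criteria, label = nm, n_perm = n_perm, seed = seed,
      max_pc = max_pc, max_ortho = max_ortho))
    if (nm == names(methods)[1] && !is.null(method_results[[nm]]))
      method1_ft <- method_results[[nm]]$feature_table
  }

  pretreatment_results <- list()
  for (nm in names(pretreatments)) {
    input <- method1_ft %||% runs
    pretreatment_results[[nm]] <- safe_run(nm, run_method(
      input, methods[[1]], pretreatments[[nm]], truth = truth,
      criteria = criteria, label = nm, n_perm = n_perm, seed = seed,
      max_pc = max_pc, max_ortho = max_ortho))
  }

  sel_of <- function(results) {
    ok <- !vapply(results, is.null, TRUE)
    lapply(results[ok], `[[`, "selection")
  }
  msel <- sel_of(method_results)
  psel <- sel_of(pretreatment_results)
  structure(list(
    method_results = method_results,
    pretreatment_results = pretreatment_results,
    method_comparison = if (length(msel) >= 2) compare_methods(msel),
    pretreatment_comparison = if (length(psel) >= 2) compare_methods(psel),
    failures = failures
  ), class = "experiment_report")
}

#' Tabulate an experiment report
#'
#' @param report An `experiment_report`.
#' @return List of two data frames, `methods` and `pretreatments`, with
#'   the per-cell statistics (feature count, noise fraction, model quality,
#'   CV-ANOVA p, permutation intercepts, validity, selection size,
#'   recovery).
#' @export
experiment_tables <- function(report) {
  row_of <- function(r) {
    if (is.null(r)) return(NULL)
    data.frame(
      label = r$label,
      mass_tolerance = r$processing$mass_tolerance,
      intensity_threshold = r$processing$intensity_threshold,
      pretreatment = pretreatment_label(r$pretreatment),
      n_features = r$table_stats$n_features,
      noise_fraction = r$table_stats$noise_fraction,
      pca_n_pc = r$pca$n_pc, pca_r2x_cum = r$pca$r2x_cum,
      pca_q2_cum = r$pca$q2_cum,
      opls_r2x_cum = r$opls$r2x_cum, opls_r2y_cum = r$opls$r2y_cum,
      opls_q2_cum = r$opls$q2_cum,
      cv_anova_p = r$validation$cv_anova$p,
      perm_r2_intercept = r$validation$permutation$r2_intercept,
      perm_q2_intercept = r$validation$permutation$q2_intercept,
      perm_valid = r$validation$permutation$valid,
      n_selected = length(r$selection$selected),
      sensitivity = if (!is.null(r$recovery)) r$recovery$sensitivity
                    else NA_real_,
      false_discovery_fraction =
        if (!is.null(r$recovery)) r$recovery$false_discovery_fraction
        else NA_real_,
      stringsAsFactors = FALSE)
  }
  list(methods = do.call(rbind, lapply(report$method_results, row_of)),
       pretreatments = do.call(rbind,
                               lapply(report$pretreatment_results, row_of)))
}

#' Write an experiment report bundle to a directory
#'
#' CSV tables per grid, comparison JSON, and a Markdown summary.
#'
#' @param report An `experiment_report`.
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- experiment_tables(report)
  if (!is.null(tabs$methods))
    utils::write.csv(tabs$methods, file.path(dir, "methods_table.csv"),
                     row.names = FALSE)
  if (!is.null(tabs$pretreatments))
    utils::write.csv(tabs$pretreatments,
                     file.path(dir, "pretreatments_table.csv"),
                     row.names = FALSE)
  comp_json <- function(cmp) {
    if (is.null(cmp)) return(NULL)
    list(methods = cmp$methods,
         jaccard = as.data.frame(cmp$jaccard),
         venn = as.list(cmp$venn),
         n_matched = nrow(cmp$membership),
         core = sum(rowSums(cmp$membership) == length(cmp$methods)),
         unique = sum(rowSums(cmp$membership) == 1))
  }
  jsonlite::write_json(
    list(method_comparison = comp_json(report$method_comparison),
         pretreatment_comparison = comp_json(report$pretreatment_comparison),
         failures = report$failures),
    file.path(dir, "comparisons.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  md <- c("# Sensitivity experiment report", "",
          "## Pre-processing methods", "",
          if (!is.null(tabs$methods)) knit_table(tabs$methods),
          "", "## Pre-treatments (Method 1 matrix)", "",
          if (!is.null(tabs$pretreatments)) knit_table(tabs$pretreatments),
          "",
          if (length(report$failures))
            c("## Failed cells", "",
              sprintf("- %s: %s", names(report$failures),
                      unlist(report$failures))))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

# minimal Markdown table renderer
knit_table <- function(df) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 4))
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(header, sep, rows)
}
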