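#!/usr/bin/env Rscript
# Score the Method-1 + Pareto selection against the planted ground truth
# (sensitivity, false discoveries) and measure held-out classification
# accuracy of the OPLS-DA model.  Reads scratch/experiment.rds when
# 02_sensitivity_experiment.R has run, else recomputes the needed cell.
# Writes results/recovery.csv.

library(metabomine)

cohort <- if (file.exists("scratch/cohort/manifest.csv")) {
  list(runs = read_runs("scratch/cohort"),
       truth = read_truth("scratch/cohort/truth.json"))
} else {
  generate_cohort(build_design())
}

m1 <- if (file.exists("scratch/experiment.rds")) {
  readRDS("scratch/experiment.rds")$method_results$Method1
} else {
  run_method(cohort$runs, processing_params(),
             pretreatment_spec(scaling = "pareto"), truth = cohort$truth,
             label = "Method1", seed = 1L)
}

rec <- m1$recovery
cat(sprintf(
  "Method-1 + Pareto selection: %d features; sensitivity %.2f (%d/%d planted recovered), %d false positive(s).\n",
  length(m1$selection$selected), rec$sensitivity, length(rec$recovered),
  sum(cohort$truth$catalog$is_discriminating &
        is.na(cohort$truth$catalog$adduct_of)),
  length(rec$false_positives)))

# Holdout: refit on a subset of samples, predict the rest.
ft <- m1$feature_table
idx_c <- which(ft$group == "C")
idx_t <- which(ft$group == "T")
test_idx <- c(idx_c[seq_len(2)], idx_t[seq_len(4)])
train_idx <- setdiff(seq_along(ft$group), test_idx)
subset_ft <- function(ft, idx) {
  ft$values <- ft$values[idx, , drop = FALSE]
  ft$sample_id <- ft$sample_id[idx]
  ft$group <- ft$group[idx]
  ft
}
train_ft <- subset_ft(ft, train_idx)
test_ft <- subset_ft(ft, test_idx)
pt <- pretreat(train_ft, pretreatment_spec(scaling = "pareto"))
model <- fit_oplsda(pt)
pred <- predict(model, apply_pretreatment(pt, test_ft))
accuracy <- mean(pred$class == test_ft$group)
cat(sprintf("Held-out classification: %d/%d correct (accuracy %.2f).\n",
            sum(pred$class == test_ft$group), length(test_idx), accuracy))

dir.create("results", showWarnings = FALSE)
write.csv(data.frame(
  n_selected = length(m1$selection$selected),
  sensitivity = rec$sensitivity,
  false_positives = length(rec$false_positives),
  false_discovery_fraction = rec$false_discovery_fraction,
  holdout_accuracy = accuracy), "results/recovery.csv", row.names = FALSE)
cat("Recovery metrics written to results/recovery.csv.\n")
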