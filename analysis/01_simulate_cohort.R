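#!/usr/bin/env Rscript
# Simulate the synthetic study cohort: 9 control / 15 treated centroid
# LC-MS runs with 200 catalog metabolites (10 discriminating at fold
# change 8), adducts and chemical noise.  Writes the runs (run-csv +
# manifest) and the ground truth under scratch/cohort/, and a catalog
# summary under results/.

library(metabomine)

out_runs <- "scratch/cohort"
out_results <- "results"
dir.create(out_results, showWarnings = FALSE, recursive = TRUE)

design <- build_design()
print(design)

cohort <- generate_cohort(design)
write_runs(cohort$runs, out_runs, format = "run-csv")
write_truth(cohort$truth, file.path(out_runs, "truth.json"))

cat_df <- cohort$truth$catalog
summary_df <- data.frame(
  class = c("background", "discriminating", "adduct"),
  n = c(sum(!cat_df$is_discriminating & is.na(cat_df$adduct_of)),
        sum(cat_df$is_discriminating & is.na(cat_df$adduct_of)),
        sum(!is.na(cat_df$adduct_of))),
  median_intensity = c(
    median(cat_df$base_intensity[!cat_df$is_discriminating &
                                   is.na(cat_df$adduct_of)]),
    median(cat_df$base_intensity[cat_df$is_discriminating &
                                   is.na(cat_df$adduct_of)]),
    median(cat_df$base_intensity[!is.na(cat_df$adduct_of)])))
write.csv(summary_df, file.path(out_results, "catalog_summary.csv"),
          row.names = FALSE)

n_ions <- vapply(cohort$runs, function(r) nrow(r$ions), 0L)
cat(sprintf(
  "Wrote %d runs to %s (%.0f-%.0f ions per run), truth catalog of %d entries.\n",
  length(cohort$runs), out_runs, min(n_ions), max(n_ions), nrow(cat_df)))
cat("Catalog summary written to", file.path(out_results, "catalog_summary.csv"), "\n")
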