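# metabomine

How much of what an untargeted LC-MS metabolomics study "finds" is decided
before any biology enters the picture — by the peak-picking parameters and
the pre-treatment of the data matrix?  `metabomine` is an R package and
analysis workflow that quantifies this question end to end.  It implements
the standard two-group data-mining pipeline:

1. **Matrix creation** from centroid LC-MS runs: region-of-interest
   construction by mass tolerance, ApexTrack-style peak detection
   (Savitzky–Golay second derivative, inflection points, local-minimum
   integration bounds), cross-sample alignment within ±0.05 Da / ±0.20 min
   windows, intensity-threshold peak removal with a noise-elimination
   fallback, and total-ion-intensity normalization;
2. **Pre-treatment**: 50% missing-value filtering, log₁₀/power
   transformation, and center / unit-variance (UV) / Pareto scaling;
3. **Modelling**: missing-value-aware NIPALS PCA with element-wise
   seven-fold cross-validation (components retained while cumulative Q²
   increases), and OPLS-DA splitting X-variation into one predictive and
   CV-chosen orthogonal components;
4. **Validation**: Hotelling's T² (strong outliers), DModX against Dcrit
   (moderate outliers), CV-ANOVA on cross-validated predictive residuals,
   and the n = 50 response permutation test with R²/Q² intercepts;
5. **Feature selection**: S-plot (p1 = cov(t, x), p(corr)1 = cor(t, x))
   with cutoffs |p1| ≥ 0.05 and |p(corr)1| ≥ 0.5, VIP > 1, and a dot-plot
   group-overlap confirmation.

Because public raw data for this kind of study are rarely available, the
package ships a **synthetic centroid-LC-MS cohort generator with planted
ground truth** (Gaussian chromatographic peaks, centroid m/z jitter,
correlated lognormal biological variation, Na-adduct redundancy, chemical
noise), so every stage — and the sensitivity of the final feature list to
mass tolerance, intensity threshold, scaling and transformation — can be
scored against a known answer.  The methods vignette
(`vignettes/data-mining-sensitivity.Rmd`) documents the models, parameter
defaults and design decisions.

## Worked example

```r
library(metabomine)

# a 9-control / 15-treated cohort, 200 metabolites, 10 discriminating at
# fold change 8, plus adducts and chemical noise
cohort <- generate_cohort(build_design())

# Method-1 style matrix creation: 0.005 Da mass tolerance, 10-count
# intensity threshold
ft <- process_cohort(cohort$runs, processing_params())
ft
#> Feature table: 24 samples (C=9, T=15) x 9465 features; 93.1% missing

pt   <- pretreat(ft, pretreatment_spec(scaling = "pareto"))
opls <- fit_oplsda(pt)
opls
#> OPLS-DA: 1 predictive + 2 orthogonal component(s), classes C/T
#>   R2X(cum) = 0.483 (pred 0.268, ortho 0.215), R2Y(cum) = 0.995, Q2(cum) = 0.957

sel <- select_features(opls, ft,
                       criteria = selection_criteria(require_no_overlap = TRUE))
evaluate_against_truth(sel, cohort$truth)[c("sensitivity",
                                            "false_discovery_fraction")]
#> $sensitivity
#> [1] 1
#> $false_discovery_fraction
#> [1] 0
```

The feature table keeps ~9.5k features at threshold 10 (97% of them
chemical-noise singletons, mostly missing across samples and dropped by
the 50% rule before modelling) versus ~210 at threshold 100; the OPLS-DA
model explains nearly all class variation (R²Y = 0.995) and predicts it
under cross-validation (Q² = 0.957); the S-plot/VIP/dot-plot selection recovers
all 10 planted discriminating metabolites with no false positives.

## The analysis workflow

The numbered drivers under `analysis/` run the full study from the
repository root and write their tables under `results/` (large
intermediates go to `scratch/`):

```sh
Rscript analysis/01_simulate_cohort.R        # cohort + ground truth
Rscript analysis/02_sensitivity_experiment.R # 4 Methods x 8 pre-treatments
Rscript analysis/03_weak_signal_grid.R       # permutation test exposes weak models
Rscript analysis/04_recovery_and_holdout.R   # truth recovery + holdout accuracy
```

`02` reproduces the study's central findings on synthetic data: raising
the intensity threshold 10 → 100 counts collapses the matrix from
thousands of mostly-noise features to a few hundred real ones; scaling and
transformation change R²X/Q², the validity flags and the selected feature
sets (shared core + method-dependent regions); `03` shows that on a
weak-signal cohort the permutation test flags the pre-treatment cells
whose high in-sample R²Y is not trustworthy.

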