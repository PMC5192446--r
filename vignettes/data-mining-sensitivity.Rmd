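---
title: "LC-MS untargeted metabolomics data mining: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LC-MS untargeted metabolomics data mining: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`metabomine` implements a complete data-mining pipeline for two-group
untargeted LC-MS metabolomics — peak detection, cross-sample alignment,
intensity thresholding, normalization, pre-treatment, latent-variable
modelling (PCA, OPLS-DA), model validation and statistical feature
selection — together with a synthetic centroid-data generator with planted
ground truth, so that the sensitivity of the end result to pre-processing
parameters (mass tolerance, intensity threshold) and pre-treatment choices
(scaling, transformation) can be quantified against a known answer.
Metabolite annotation, pathway analysis, QC-based drift correction and
negative-ionization data are out of scope.

This vignette explains the models and algorithms, the tunable parameters
and their defaults, what the synthetic generator does and does not emulate,
and the numerical and design decisions that were genuinely open.

# The synthetic cohort generator

Because the pipeline's behaviour can only be *scored* when the truth is
known, the generator is a first-class module, not a test fixture.  It
emulates a positive-mode centroid UHPLC-MS acquisition of a two-group
plant-extract study: 9 control (C) and 15 treated (T) samples by default,
m/z 100–1000 Da, retention time 1–15 min, one scan every 0.005 min.

Each of the default 200 catalog metabolites (190 shared background, 10
discriminating) is placed uniformly in the Rt × m/z window and appears in
every sample as a Gaussian chromatographic peak:

* apex height = the sample's realized intensity, SD `peak_sigma_rt`
  (default 0.02 min, so the 5%-height width of ~0.1 min spans ~20 scans —
  comfortably above the detectability floor of ~10 scans per peak);
* per-scan centroid m/z = catalog m/z + Gaussian jitter
  (`mz_jitter_sd` = 0.001 Da, truncated at 4 SD — a calibrated instrument's
  mass error is bounded, and the truncation makes "every ion within 4 SD of
  its catalog entry" an exact invariant rather than a probabilistic one).

Realized intensities are `base × fold_change^(treated) × ε`, with `ε`
lognormal, mean 1, coefficient of variation `intensity_cv` (default 0.2 —
a typical between-plant biological CV).  Two structural choices deserve
explanation because naive alternatives produce *unrealistic statistical
behaviour* downstream:

* **Correlated biological variation.**  The log-noise is split between a
  latent block factor shared by the metabolite's co-regulation group
  (`n_latent_factors` = 5, `latent_variance_share` = 0.5) and an individual
  residual.  Metabolite intensities in real extracts co-vary strongly
  (pathway stoichiometry, shared regulation).  With fully independent
  features and N = 24 ≪ K, the data matrix is effectively full rank in
  sample space and a *permuted-label* OPLS-DA can reproduce any response
  almost perfectly in-sample — the permutation test's R² criterion would
  then reject every model, valid or not.  With block correlation the
  permuted R²Y falls to the 0.5–0.9 range while a genuine fold-change-8
  model stays above it, the same regime the response-permutation test
  operates in on real data.
* **Discriminating metabolites as minor TIC constituents.**  Their control
  apex intensities are drawn log-uniform on 50–300 counts (~2% of the total
  ion current), as induced defence metabolites typically are.
  Total-ion-intensity normalization divides each sample by its feature sum;
  if the planted effects dominated the TIC, normalization would imprint a
  mirror-image of the group effect on *every* background feature (the
  closure artifact) and flood the selection with false positives that no
  parameter choice could remove.

Redundant ions are modelled as [M+Na]⁺ companions (+21.9819 Da) carried by
each metabolite with probability 0.2, whose realized intensity is a fixed
per-adduct fraction of the parent's (log-uniform on 0.10–0.50, drawn once
per adduct): perfectly correlated with the parent before measurement noise,
and — because formation efficiency varies — straddling the detection
thresholds, which is what makes the redundancy visible to the
parameter-sensitivity experiment.  Chemical noise is drawn per scan
(0.2 ions/scan, uniform in m/z, intensity uniform on 1–30 counts): the
sub-threshold clutter that the intensity-threshold parameter exists to
remove.

**What the generator does not emulate:** retention-time drift between
runs, instrument signal drift over a batch (QC-correctable in real
studies), profile-mode peak shapes, isotope envelopes, detector
saturation, heteroscedastic (intensity-dependent) measurement error, and
missingness mechanisms other than sub-threshold signal.  Passing tests on
synthetic data therefore demonstrate the *internal correctness and
qualitative behaviour* of the pipeline, not its field performance on any
particular instrument.

# Matrix creation

**ROIs.**  Ions of one run are clustered greedily in ascending m/z order:
an ion joins the region of interest whose running intensity-weighted m/z
center lies within `mass_tolerance`, else it seeds a new ROI.  Every
in-range ion belongs to exactly one ROI.  The two study values of
`mass_tolerance` are 0.005 and 0.01 Da (the instrument mass accuracy and
twice it).

**Peak detection.**  Each ROI's EIC (on the run's scan grid, zero where
the ROI has no ion) is smoothed with a Savitzky–Golay filter and the
second derivative is taken from the same polynomial fit.  Candidate peaks
are maximal runs of negative second derivative; the run bounds act as the
inflection points; the apex is the *raw* EIC maximum inside the run.
Integration bounds extend outward along the smoothed trace to the nearest
local minimum (the valley towards an unresolved neighbour, or the flat
baseline); a straight baseline is drawn between the bounds; height is the
raw apex above the baseline and area the trapezoidal integral above it.
Two numerical choices here:

* *Bounds at local minima, not at the 5%-height crossing.*  Anchoring the
  baseline at the 5%-of-height crossings systematically clips ~10% of a
  Gaussian peak's area (the chord sits at 0.05·h across ~5σ); with
  local-minimum bounds the recovered area of a noiseless Gaussian is within
  2% of the closed form h·σ·√(2π).  The 5% level is retained as the
  reported `width_5pct` statistic and for the auto-estimated peak width.
* *Quantification on the raw trace.*  Smoothing-induced height attenuation
  would otherwise make a peak's recorded height depend on the smoothing
  window rather than on the detector counts.

Candidates are dropped when their height falls below
`baseline_threshold` (default 3) times a robust local noise estimate
(1.4826 · MAD of the raw-minus-smoothed residual over the ROI
neighbourhood — a workable stand-in for the vendor's undisclosed
inflection-slope noise estimator), or below the `noise_elimination_level`.
In `"auto"` mode the peak width is estimated as the median 5%-height width
of the 20 tallest raw EIC maxima of the run and the smoothing window is
set to about half that width (wide enough to suppress scan noise, narrow
enough not to distort the peak), with polynomial order 3.

**Alignment.**  Peaks pooled over runs are clustered greedily in
descending height order into features: a peak joins the nearest existing
feature (scaled distance `(Δmz/0.05 Da)² + (Δrt/0.20 min)²`) whose windows
contain it and whose slot for that sample is empty, else it seeds a new
feature.  Greedy descending-height clustering is deterministic and
O(n log n); tall, reliable peaks define the consensus coordinates that
weaker peaks then join.

**Thresholding.**  A feature is kept iff some sample reaches
`intensity_threshold` (study values 10 and 100 counts); within a kept
feature the per-sample threshold is lowered to `noise_elimination_level`
(default `intensity_threshold/10`, a configurable stand-in for an
unpublished vendor setting), below which values become missing.

**Normalization.**  Each sample's non-missing feature heights are rescaled
to sum to 10 000 counts.  The target is arbitrary (downstream scaling
removes it); a fixed constant keeps tables comparable across runs of the
pipeline.

# Pre-treatment

Transform first, then scale; scaling statistics are computed on the
transformed values (the convention under which "UV Log" and "Pareto Power"
combinations are named).  The transformations are
`y = log10(C1·x + C2)` and `y = (C1·x + C2)^C3` with C1 = 1, C2 = 0,
C3 = 2.  With C2 = 0 a zero intensity has no defined log; such cells
become *missing* (counted and reported) rather than an error or a
pseudo-count — the downstream NIPALS is missing-aware, and inventing a
pseudo-count would silently change the data.  Scalings are column-wise
center `x − m`, UV `(x − m)/s` and Pareto `(x − m)/√s`, with `s` the
sample (n−1) standard deviation — stated explicitly because conventions
differ.  Zero-variance columns get weight 0 and are excluded from
modelling rather than dropped, so matrix dimensions remain reportable.
Features, then samples, with more than 50% missing values are removed
first.  Per-column centers and weights are stored so the pre-treatment is
exactly invertible and applicable to new observations.

# Latent-variable models

**NIPALS PCA with missing values.**  Components are extracted one at a
time by alternating score/loading regressions computed over non-missing
cells only.  A sparsely observed row or column would otherwise receive
extrapolated leverage: the per-element denominator scale N/(non-missing
count) is capped at a correction factor of 3.0 (rows/columns observed in
less than a third of their cells are not amplified further).  The exact
behaviour of the commercial implementation this mirrors is undocumented,
so the cap is togglable (`correction_factor = Inf` disables it).
Convergence is declared at a relative score change below 1e-10; up to
5000 iterations are allowed per component — near-degenerate noise
components of small matrices converge at the power-iteration rate
(λ₂/λ₁)^k and routinely need more than a few hundred iterations; a tight
tolerance with a generous iteration cap keeps "NIPALS ≡ truncated SVD on
complete data" testable at 1e-6 without spurious failures.
Non-convergence is an error, never a silent truncation.

**Cross-validation and the R1 rule.**  PCA is validated by element-wise
seven-fold deletion: cells are assigned to groups by `(row + col) mod 7`,
each group is predicted by a model fit without it, and
`Q²_a = 1 − PRESS_a / SS_(a−1)` with `SS_(a−1)` the residual sum of squares
of the full-data model.  Components are retained while cumulative Q²
increases (each marginal Q² > 0) — the "significant component" rule.
Observation-wise deletion would be the wrong unit here: PCA has no
response, and deleting whole rows tests row reconstruction, not the
model's cell-level predictive structure.

**OPLS-DA.**  The class is encoded 0/1 and centered (the encoding is
inert: predictions use the midpoint of the fitted class means).  The
predictive weight is `w ∝ Xᵀy`; orthogonal components are extracted by
deflating the part of each X-loading orthogonal to `w`, repeated while the
seven-fold *observation-wise* cross-validated Q² increases (up to
`max_ortho`), then the final predictive component is computed on the
deflated matrix.  CV folds are class-stratified and assigned round-robin
after sorting sample ids — deterministic by construction, so identical
inputs give identical models.  R²X is bookkept separately for the
predictive and orthogonal parts; Q² is the cross-validated fraction of
response variance predicted.

# Model validation

* **Hotelling's T²** per observation with the F-based 95% normality-area
  limit `A(N−1)/(N−A) · F₀.₉₅(A, N−A)`: strong outliers.
* **DModX**: per-observation residual SD normalized by the pooled
  residual SD, flagged against
  `Dcrit = √F₀.₉₅(K−A, (N−A−1)(K−A))`: moderate outliers.  With missing
  cells the residual sum is rescaled by K/K(observed) before applying the
  complete-data degrees of freedom.
* **CV-ANOVA**: `F = ((SS_y − PRESS)/df₁)/(PRESS/df₂)` on the
  cross-validated predictive residuals, with `df₁` = (predictive +
  orthogonal components) + 1 model parameters and `df₂ = N − df₁`.  The
  exact degrees-of-freedom bookkeeping of the commercial implementation is
  proprietary; this allocation is covered by a null-simulation tolerance
  (type-I error ≤ 0.1 at nominal 0.05) rather than an exact-match claim.
* **Response permutation test** (n = 50): the class vector is shuffled
  with class sizes preserved (9/15), the full OPLS-DA — including the
  orthogonal-component selection — is refit to each permuted response, and
  (label correlation, R²Y, Q²) are recorded.  Intercepts at correlation 0
  come from least-squares lines through the permuted points plus the true
  model at correlation 1 (the usual convention; a permuted-points-only
  regression is available by flag).  A model is *valid* when its R²Y and
  Q² exceed every permuted value.  Note that at N = 24 a permuted model's
  Q² is *not* reliably negative: the cross-validated Q² has a wide null
  distribution at this sample size, and a shuffled label vector retains
  some correlation with the true one (class sizes are preserved) and can
  legitimately borrow predictive power from real structure — which is
  precisely why the permutation plot regresses R²/Q² against label
  correlation and judges the intercept, rather than expecting every
  permuted Q² to be negative.  The leak-freeness of the CV machinery
  itself is verified separately at a sample size (N = 96) where the null
  distribution concentrates below zero.

# Feature selection

On the predictive component: `p1 = cov(t, x_k)` (influence) and
`p(corr)1 = cor(t, x_k)` (reliability) form the S-plot; VIP combines the
predictive and orthogonal components with dimensionless variance shares
(explained y-fraction for the predictive component, explained X-fractions
for the orthogonal ones), normalized so mean VIP² = 1; a
predictive-only variant is available since displays differ on this.  The
default cutoffs are |p1| ≥ 0.05, |p(corr)1| ≥ 0.5 and VIP > 1.0.  The p1
axis is the plain covariance — commercial S-plots scale this axis by an
undocumented constant, so the 0.05 cutoff applies to the covariance
definition here and is configurable.  "VIP well above 1" is
operationalized as the exposed threshold `vip_min = 1.0`.

The dot-plot confirmation — "a very strong discriminating variable has no
overlap between groups" — is reduced to a testable number: the overlap of
the two groups' [min, max] ranges of normalized intensity, as a fraction
of their union range (0 = disjoint).  The pipeline's default selection
requires zero overlap, mirroring the workflow in which every S-plot/VIP
candidate is confirmed on a dot plot before being accepted; the bare
S-plot/VIP rule is available through `selection_criteria()`.

# The sensitivity experiment

`run_experiment()` crosses the four canonical pre-processing parameter
sets (mass tolerance 0.005/0.01 Da × intensity threshold 10/100 counts,
under Pareto scaling) with the eight canonical pre-treatments (None,
Center, UV, Pareto × no transform; UV/Pareto × log/power, on the
Method-1 matrix, computed once and reused).  Selected feature sets are
compared by (Rt, m/z)-window matching — methods differ in mass tolerance,
so feature-id strings are not comparable across cells — giving Jaccard
similarities and the full Venn region decomposition, plus recovery
(sensitivity, false-discovery fraction, with adduct hits credited to their
parent metabolite) against the synthetic truth.  A failing grid cell is
recorded as a result, not a fatal error: statistically invalid cells are
themselves findings.

Problem sizes throughout (24 samples, 200 metabolites, 0.2 noise
ions/scan, 50 permutations, 5000-draw coverage simulations) were chosen so
the full experiment and its validation battery run comfortably on a single
CPU while keeping every statistical check adequately powered.

# Known limitations

* The ApexTrack-style detector is a published-behaviour reconstruction of
  an undisclosed vendor algorithm; it matches the *described* operations
  (second derivative, inflection points, 5% width, baseline threshold,
  Savitzky–Golay smoothing), not the vendor's numerical output.
* The noise-level statistic reported for a feature table is the fraction
  of features not matching the synthetic catalog — real data offers no
  such oracle, and the vendor's "Noise Level (%)" definition is not
  public.
* Rt warping between samples is not modelled or corrected; alignment uses
  fixed windows only.
* CV-ANOVA's F-approximation at N = 24 is approximate; its nominal level
  is verified by simulation within a documented tolerance, not exactly.
* The permutation R² criterion depends on the correlation structure of the
  feature space (see the generator notes): on data with few effective
  dimensions it is conservative, on nearly independent features it rejects
  everything.
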