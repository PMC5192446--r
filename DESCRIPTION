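Package: metabomine
Title: Sensitivity of LC-MS Untargeted Metabolomics Data Mining to
    Pre-Processing and Pre-Treatment Choices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for untargeted LC-MS metabolomics data
    mining: centroid peak detection on extracted ion chromatograms
    (Savitzky-Golay second-derivative apex tracking), cross-sample peak
    alignment, intensity-threshold peak removal with a noise-elimination
    fallback, total-ion-intensity normalization, data pre-treatment
    (log/power transformation; centering, unit-variance and Pareto
    scaling), missing-value-aware NIPALS principal component analysis
    with seven-fold cross-validation, OPLS-DA with S-plot/VIP feature
    selection, and model validation by Hotelling's T-squared, DModX,
    CV-ANOVA and response permutation testing.  A synthetic centroid
    LC-MS cohort generator with planted ground truth supports a
    sensitivity experiment quantifying how mass tolerance, intensity
    threshold, scaling and transformation change model quality and the
    set of selected discriminating features.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
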