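Package: iridens
Title: Corneal Densitometry, Brightness Artefacts and Objective Iris Color
    from Anterior-Segment Images
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies corneal densitometry (mean pixel intensity of the
    segmented cornea) and iris-driven brightness artefacts in Scheimpflug-style
    anterior-segment images, using an adaptive per-frame intensity threshold
    (corneal mean plus three standard deviations). Computes an objective,
    continuous iris-pigmentation index from slit-lamp photographs by
    converting to CIELAB, robustly normalizing each component by the cohort
    median and interquartile range, and combining them into a single scalar
    (IrisColor = -Ln + an + bn) whose sign separates light from dark irises.
    Provides the statistical layer linking densitometry to pigmentation
    (Pearson correlation, linear mixed-effects models with a per-subject
    random intercept, light/dark group comparison and bias summaries) and
    seeded synthetic phantom and cohort generators with recorded ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    EBImage,
    lme4,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Visualization, Preprocessing
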