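Package: ecgmi
Title: Myocardial Infarction Detection and Localization from 12-Lead ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end toolkit for beat-level myocardial infarction (MI)
    detection (2-class) and localization (6-class) from standard 12-lead
    electrocardiograms. Provides a synthetic PTB-like 12-lead ECG cohort
    generator with class-conditioned MI morphology (ST displacement,
    pathological Q waves, T-wave inversion), a reader/writer for the PTB
    dialect of the WFDB format, the preprocessing chain (anti-aliased
    downsampling to 100 Hz, median-filter baseline removal, Christov
    adaptive-threshold R-peak detection, fixed-window beat segmentation),
    balanced dataset construction with subject-disjoint repeated k-fold
    cross-validation, multi-lead multi-scale feature-concatenate
    convolutional networks (N-Net / MSN-Net) trained with Adam and early
    stopping, a (scales x filters) grid search, and clinical evaluation
    (accuracy, sensitivity, specificity, F1, ROC/AUC) with Mann-Whitney U
    model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
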