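Package: radshift
Title: Site Confounding and Generalization Auditing for Image Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-site chest-radiograph-like imaging studies with
    site-specific acquisition artifacts (corner metal tokens, text banners,
    inverted color schemes) correlated with disease prevalence, and provides a
    tested pipeline to demonstrate and audit shortcut learning in
    convolutional image classifiers: patient-level cohort splitting,
    engineered-prevalence cohort subsampling, n-gram Lasso report labeling, a
    small from-scratch CNN with plateau learning-rate scheduling, subregion
    class-activation auditing, and evaluation statistics (Mann-Whitney AUC
    with DeLong inference, Clopper-Pearson intervals, chi-square tests,
    fixed-sensitivity screening operating points, calibration summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
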