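Package: ipss
Title: Prolactin-Adjusted Interpretation of Inferior Petrosal Sinus Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting inferior petrosal sinus sampling (IPSS)
    procedures in ACTH-dependent Cushing syndrome. Computes sinus-to-peripheral
    ACTH ratios, peak ratios over configurable time windows, and four
    prolactin-adjustment methods (basal and concurrent denominators applied to
    the peak ratio or to every time point); classifies procedures as pituitary
    (CD) versus ectopic (EAS) under named threshold rule sets; and evaluates
    diagnostic performance (contingency counts, sensitivity/specificity, ROC
    curves with Youden-optimal cut-offs, single-time-point accuracy, Fisher's
    exact confounding checks). Includes a seedable synthetic cohort generator
    reproducing the statistical structure IPSS analysis assumes: central ACTH
    gradients, CRH-stimulated kinetics, a shared catheter-dilution confound,
    universal pituitary prolactin gradients, assay noise and truncation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
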