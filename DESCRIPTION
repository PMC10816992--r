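Package: abratio
Title: Plasma Abeta42/Abeta40 Ratio Thresholds for Brain Amyloid Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines positivity thresholds for the plasma amyloid-beta
    42/40 concentration ratio used to screen for brain amyloidosis, and
    converts a threshold's sensitivity and specificity into posttest
    probabilities at a given pretest prevalence. Implements the
    interquartile-range outlier filter, a two-component unequal-variance
    Gaussian mixture fitted by expectation-maximisation with the
    component-intersection cutoff, a depth-one Gini decision stump, the
    empirical ROC curve with trapezoidal AUC, DeLong and bootstrap
    confidence intervals and the Youden-index cutoff, and the likelihood
    ratio / pretest-odds calculus. A seeded synthetic-cohort generator
    emulates the bimodal ratio distribution, group- and age-dependent
    amyloid prevalence, APOE epsilon-4 enrichment, MMSE structure and
    blood-to-amyloid measurement delays, so the whole analysis is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
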