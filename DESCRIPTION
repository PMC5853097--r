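Package: fattyroc
Title: Individual-Level Evaluation of Erythrocyte Fatty Acid Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control evaluation of erythrocyte-membrane fatty acid
    panels as candidate diagnostic biomarkers. Implements a normality-gated
    two-sample test selection tree (Anderson-Darling, F, Student's t,
    Welch, Kolmogorov-Smirnov, Mann-Whitney U), kernel-density-based
    95 percent intervals and C-statistics (area under the ROC curve,
    both as a PDF double integral and empirically), Fisher discriminant
    multivariate classification, NIPALS partial least squares and its
    kernel extension for severity regression, seafood-intake correlation
    tables, a priori power/sample-size calculation, and recovery of data
    points from raster scatter plots by normalized cross-correlation
    template matching. A Gaussian-copula synthetic cohort generator
    reproduces the marginal structure of a two-cohort fatty acid panel so
    the entire pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr,
    png,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
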