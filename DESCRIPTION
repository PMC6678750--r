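Package: tlbscore
Title: Thermal Liquid Biopsy Thermogram Deconvolution and Diagnostic Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for serum differential scanning calorimetry
    (DSC) thermograms used as a thermal liquid biopsy (TLB). Reads, resamples
    and baseline-corrects per-subject excess heat capacity traces,
    deconvolutes each thermogram into six logistic (Hubbert) transitions by
    bounded nonlinear least squares, derives the 14-parameter TLB feature set
    (weighted moments, normalized areas, height-polygon areas and relative
    distances to a healthy reference), and fits binomial logit models whose
    fitted probability score classifies thermograms as unaltered or altered.
    Includes univariate statistics (quartiles, adapted Cohen d, ROC with
    Youden cut-off, Kruskal-Wallis and Fisher tests), confusion metrics with
    diagnostic odds ratio and exact confidence intervals, leave-one-out
    cross-validation, nested model comparison, and a seeded synthetic-cohort
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    minpack.lm,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
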