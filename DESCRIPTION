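Package: vwmix
Title: Mixture Modelling of Continuous-Report Visual Working Memory Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of dual-feature continuous-report visual working memory
    experiments. Recall responses on circular feature spaces (orientation,
    colour hue) are decomposed into target, nontarget (misbinding/swap) and
    uniform (guessing) components with a three-component von Mises mixture
    model fit by multi-start expectation-maximization. Includes chance-corrected
    circular recall precision, a nonparametric nontarget-deviation analysis,
    cross-feature error correlations, a synthetic aging-cohort generator
    emulating a two-load, two-exposure dual-feature design, and the cohort-level
    statistical pipeline (outlier screening, age regressions, repeated-measures
    ANCOVA with age as a continuous covariate, dependent-correlation
    comparisons, age-quartile summaries, and partial correlations with memory
    span scores).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
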