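Package: rtmest
Title: Regression to the Mean Effects in Pre-Post Evaluations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying regression to the mean (RTM) when a
    subgroup is selected by a cutoff on a noisy pre-test measure.
    Provides the closed-form normal-theory RTM estimator (standardized
    cutoff, Mills-ratio factor, expected subgroup pre- and post-test
    means, multi-pretest adjustment), an empirical actual-versus-
    calculated comparison on paired pre/post data with bootstrap
    standard errors and confidence intervals, a Monte Carlo validation
    study for bivariate-normal cohorts with quantile-based selection,
    pre-test score correction and net-treatment-effect adjustment, and
    seedable synthetic-data generators (bivariate normal and skewed
    Gaussian-copula fixtures) for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
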