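Package: normtrade
Title: Bias-Variance Trade-Off in Continuous Test Norming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation machinery for studying how the flexibility of a
    distributional-regression norming model trades bias against variance in
    estimated normalized z scores. Provides the skew Student t (mean-SD
    parameterized) and Box-Cox Power Exponential distributions with their
    link functions, penalized maximum-likelihood fitting of GAMLSS-style
    models (orthogonal polynomials and P-splines per distributional
    parameter, smoothing selected by GAIC), factorial population models over
    an age range, normative-sample generation, normalized z-score norming
    with centile curves, Monte-Carlo bias/variance/RMSE evaluation on an
    age-by-score grid, a full study runner, and worm-plot diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
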