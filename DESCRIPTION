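Package: bloodgas
Title: Arterial Blood Gas Interpretation and Diagnostic-Accuracy Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Point-of-care style interpretation of arterial blood gas samples:
    internal-consistency (Henderson) and life-threat safety screening,
    physiological acid-base classification into nine categories with anion-gap,
    delta-ratio and compensation analysis, oxygenation assessment (PaO2/FiO2
    with Berlin ARDS bands, age-adjusted alveolar-arterial gradient), and renal
    assessment (BUN:creatinine ratio, urea reduction ratio, Kt/V). Includes the
    validation machinery for diagnostic-accuracy studies of such classifiers:
    three-rater adjudication, observed agreement and Cohen's kappa with
    asymptotic confidence intervals, per-category one-vs-rest accuracy with
    Wilson score intervals, predictive values and likelihood ratios, plus a
    seeded generator of physiologically coherent labelled cohorts and simulated
    imperfect raters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
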