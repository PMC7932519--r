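Package: affectnet
Title: Dynamic Networks of Momentary Affect States from Experience
    Sampling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating and comparing group-level temporal
    networks of momentary affect states measured with the experience
    sampling method (ESM). Provides a synthetic ESM cohort generator with
    known vector-autoregressive ground truth (twin-family structure,
    semi-random beep schedules, Likert observation, missingness),
    preprocessing (person-mean centering, same-day lag pairing, item
    diagnostics), symptom-change group composition with multiverse
    variants, multilevel lagged regression models with AR(1) residuals
    fitted per affect state, network summary statistics (negative
    connectivity, out-strength centrality, cross-valence effects,
    reinforcing-cycle detection), and permutation tests for group
    differences in network metrics.
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
    nlme,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
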