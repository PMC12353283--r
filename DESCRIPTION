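Package: lefttruncsim
Title: Monte Carlo Quantification of Left-Truncation Bias in Perinatal
    Cohort Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates conception cohorts of implanted conceptuses to
    quantify selection bias from left truncation when perinatal cohort
    entry is restricted to pregnancies surviving past 20 weeks of
    gestation. Cohorts carry binary abnormal placentation, early
    placental-abruption onset, spontaneous abortion as a censoring event,
    and perinatal mortality or stillbirth as the outcome, all generated
    from multiplicative risk models. The package builds factorial
    scenario grids, simulates replicate cohorts by nested binomial
    sampling, estimates stratified risks, risk differences and risk
    ratios in both the full conception cohort and the left-truncated
    birth cohort, computes absolute and relative bias estimands, and
    validates every simulated quantity against closed-form expectations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
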