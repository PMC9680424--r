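Package: redeye
Title: Dynamic Bayesian Differential Diagnosis and Triage for Red Eye
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A knowledge-base-driven engine for sequential Bayesian diagnosis
    of the acute red eye. Maintains a ranked differential diagnosis over a
    configurable set of ocular conditions, updates it after every Yes/No/I
    don't know answer, and chooses the next question dynamically by the
    potential pre-test to post-test probability change (a total-variation
    value-of-information score) under prerequisite and redundancy
    constraints. Includes interactive and batch front-ends, management
    advice rules, urgency triage, evaluation statistics (top-k accuracy,
    sensitivity and specificity with exact Clopper-Pearson binomial
    confidence intervals), and a synthetic patient generator for end-to-end
    testing.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
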