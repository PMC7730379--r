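Package: spoturine
Title: Monte Carlo Simulation of Urinary Biomarker Reliability for
    Non-Persistent Chemicals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates populations of individuals orally exposed to a
    non-persistent chemical with a one-compartment first-order absorption
    pharmacokinetic model, generates void-by-void urinary biomarker
    concentrations on realistic synthetic urination schedules, and
    quantifies how the reliability of spot-urine exposure assessment
    (regression R-squared against the internal-dose AUC, tertile and
    quartile classification accuracy, and the one-way ANOVA intraclass
    correlation coefficient) improves with the number of urine samples
    collected and pooled.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
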