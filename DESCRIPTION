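Package: aesignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for pharmacovigilance signal detection on spontaneous
    adverse-event report extracts in the style of OpenVigil/FAERS exports.
    Reads, validates and deduplicates report records; maps MedDRA preferred
    terms onto a hierarchical catalog of standardized MedDRA queries (SMQs);
    computes the four standard disproportionality statistics (reporting odds
    ratio, proportional reporting ratio, the Bayesian confidence propagation
    neural network information component, and the empirical Bayes geometric
    mean from the multi-item gamma-Poisson shrinker) with interval bounds and
    a joint positive-signal rule; produces descriptive cohort tables
    (drug shares, demographics, yearly trends, serious-outcome rates) and
    stratified subgroup analyses; and includes a synthetic spontaneous-report
    generator with known ground truth for validating every stage.
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
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
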