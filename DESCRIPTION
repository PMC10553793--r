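Package: mstowl
Title: Outcome-Weighted Learning for Individualized Treatment Rules with
    Multistate Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of optimal individualized treatment rules from
    right-censored multistate process data collected in two-arm randomized
    trials.  Patient preferences over health states enter through weighted
    restricted state-occupation utilities; censoring is handled by inverse
    probability of censoring weighting based on the Nelson-Aalen estimator
    of the censoring hazard; rules are estimated by penalized weighted
    hinge-loss (support-vector style) minimization over linear or Gaussian
    kernel decision classes.  Includes plug-in and leave-one-out (jackknife)
    value estimation, influence-function standard errors, simultaneous
    confidence intervals over preference-weight sets via Gaussian multiplier
    simulation, and a progressive illness-death trial simulator with
    closed-form true-value evaluation for method validation.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    Matrix,
    optparse,
    survival,
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
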