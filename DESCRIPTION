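Package: condcorr
Title: Conductance Correlations and Activity Type in Model Neuron Databases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing how pairwise linear correlations between
    ion-channel maximal conductances relate to the intrinsic electrical
    activity of conductance-based model neurons. Simulates grid databases of
    single-compartment stomatogastric-style model neurons (eight maximal
    conductances, exponential-Euler integration), classifies each model's
    intrinsic activity (silent, spiking, bursting, with burst metrics such as
    duty cycle, slow-wave amplitude and rise-phase slopes), partitions the
    database into activity-defined sub-populations, screens every conductance
    pair for linear dependence with a raw chi-squared independence statistic
    and Spearman rank correlation, and quantifies how imposing an observed
    correlation enriches a target activity type via correlation-based
    populations with matched random controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
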