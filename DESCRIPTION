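Package: idudyn
Title: Dynamic Transmission Modelling of Injection Drug Use Initiation
    and Opioid Agonist Treatment Scale-Up
Version: 1.0.0
Authors@R:
    person("Morgan", "Carver", email = "morgan.carver@example.org",
           role = c("aut", "cre"))
Description: A deterministic compartmental model of injection drug use (IDU)
    initiation in which people who inject drugs (PWID) "transmit" injection
    initiation to injection-naive drug users, modulated by opioid agonist
    treatment (OAT) enrollment and by history of assisting initiations.
    Provides Monte Carlo sampling of the epidemiological parameter space,
    exact equilibrium calibration to prevalence and coverage targets,
    projection of OAT coverage scale-up scenarios with percentile uncertainty
    intervals, partial-rank-correlation and one-way sensitivity analyses,
    modified Poisson regression with robust (sandwich) variance for binary
    outcomes, REML random-effects pooling of log relative risks, and a
    synthetic multi-site cohort generator for validating the statistical
    machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
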