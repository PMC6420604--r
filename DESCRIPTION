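Package: ictalloop
Title: Closed-Loop Optogenetic Seizure Analytics for Single-Channel ECoG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for simulating and analysing closed-loop optogenetic
    seizure experiments on single-channel electrocorticogram (ECoG)
    recordings. Provides a seeded synthetic generator of pilocarpine-like
    epileptiform activity with ground truth (quiescent baseline, interictal
    bursts, discrete seizures with sentinel spikes, continuous epileptiform
    activity, and per-condition photostimulation effects on seizure
    duration); extraction of twenty per-epoch features from 10-s segments;
    a random-forest network-state classifier with a 2x confidence rule for
    mixed-state exclusion and an LDA projection; an online voltage-threshold
    seizure detector with alternate-trial stimulation scheduling; and the
    paired stimulated-versus-control seizure-duration analysis with the
    control-substitution rule, a reshuffled pseudo-stimulation null, window
    (pre/during/post light) analysis, and per-animal statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    MASS,
    pROC,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
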