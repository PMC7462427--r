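Package: netreconf
Title: Dynamic Network Reconfiguration Analysis for Perturbational EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trial-wise debiased weighted phase lag index (dwPLI)
    connectivity in tapered sliding peri-stimulus windows, band-specific
    multilayer community detection by greedy modularity maximization with
    ordinal interlayer coupling, null-calibrated selection of the
    structural and temporal resolution parameters, and network
    reconfiguration metrics (flexibility, allegiance) with
    distance-from-stimulation summaries. Includes a coupled-oscillator
    synthetic data generator that plants band-specific community structure
    and a mid-epoch coupling perturbation, so the full pipeline can be
    exercised and validated end-to-end without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    mclust,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
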