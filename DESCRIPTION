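Package: caedbs
Title: Closed-Loop Deep Brain Stimulation Control of a Thalamocortical
    Absence-Epilepsy Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a three-neuron (thalamic relay, cortical, reticular)
    conductance-based model of childhood absence epilepsy with synaptic
    transmission delays, and closes the loop with an adaptive fuzzy terminal
    sliding-mode controller that shapes continuous deep-brain-stimulation
    currents so the epileptic plant tracks the normal-state membrane voltages.
    Includes ideal-knowledge, adaptive-fuzzy and super-twisting sliding-mode
    baseline controllers, generators for the experimental conditions (random
    initial states, gamma-process disturbance pulse trains, low-pass-filtered
    parameter drift), single-trial and batched experiment harnesses with
    tracking root-mean-square-error and chattering metrics, and ggplot2-based
    result graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
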