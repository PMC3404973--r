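Package: hergmarkov
Title: Markov Modelling of hERG Channel Gating and Its Modulation by
    Long-Chain Acylcarnitines
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating and analysing the rapid delayed rectifier
    potassium current (I_Kr) carried by the hERG channel. Implements a
    five-state Markov chain of hERG gating (three closed states, one open,
    one inactivated) with voltage-dependent transition rates for a control
    saline condition and for extracellular palmitoyl-carnitine, a
    voltage-clamp protocol simulator (current-voltage, single-step tail and
    two-pulse availability families), the standard patch-clamp analyses
    (two-exponential deactivation fits, Boltzmann activation/availability
    fits), Nelder-Mead estimation of Markov rate constants from current
    traces, and a human endocardial ventricular action-potential model in
    which the Markov chain replaces the Hodgkin-Huxley I_Kr formulation.
    A synthetic-data module generates noisy tail currents and per-cell
    cohorts for validating every analysis stage.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
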