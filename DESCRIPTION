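Package: tracekin
Title: Single-Molecule Current-Trace Simulation, Idealization and Kinetic
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the kinetic analysis of single-molecule electrical
    recordings of conformational and binding dynamics, such as those produced
    by nanowire field-effect transistor biosensors monitoring an intrinsically
    disordered protein folding and binding its partner. Simulates
    continuous-time Markov kinetic schemes into realistic current traces
    (Gillespie sampling, 1/f plus white noise, anti-alias filtering),
    idealizes noisy traces with a Gaussian-emission hidden Markov model
    (Baum-Welch/Viterbi, with a half-amplitude threshold baseline), extracts
    dwell tables and fits left-truncated exponential mixtures, and estimates
    binding and thermodynamic parameters: Hill dissociation constants,
    Arrhenius activation energies, van't Hoff enthalpy/entropy, dynamic
    disorder statistics, observed binding rates and two-step induced-fit
    parameters, including apparent affinities under competitive binding.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
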