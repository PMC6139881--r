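Package: kintraffic
Title: Lattice-Gas Modelling of Kinesin-1 Traffic on Microtubule Protofilaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic and mean-field modelling of collective kinesin-1
    transport along microtubule protofilaments. Motors are dimers on a 1D
    lattice subject to exclusion, Langmuir attachment/detachment kinetics,
    facilitated (crowding-induced) detachment of the rear motor of an
    adjacent pair, and optional stochastic switching into an inactive
    (paused) state. Provides an exact Gillespie simulator with run-record
    and trajectory output, closed-form and iterative mean-field predictions
    of density, current, dwell time, velocity, run length and landing rate,
    a frame-based detector of periods of no or slow motion with
    censored-exponential correction, a traffic-jam amplification theory for
    pause frequencies, and weighted least-squares estimation of the
    attachment and facilitated-detachment rates from concentration-series
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    purrr,
    rlang,
    tidyr,
    ggplot2,
    stats,
    utils,
    readr,
    jsonlite,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
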