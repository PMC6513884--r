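Package: pscradle
Title: Ion Microdomain Formation at the Astrocytic Perisynaptic Cradle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multi-compartment biophysical simulator of ion dynamics at the
    astrocytic perisynaptic cradle (PsC). A Hodgkin-Huxley presynaptic neurone
    drives glutamate-release events; astrocytic EAAT1/2 transporters convert
    each event into Na+ influx and K+ counter-transport, the Na+/K+-ATPase and
    Kir channels handle K+ homeostasis, and Poole-Frenkel well-hopping
    transport along the thin astrocyte process restricts cation efflux so that
    Na+, K+ and Ca2+ microdomains form. A rising Na+ microdomain reverses the
    Na+/Ca2+ exchanger (NCX), importing Ca2+ into the cradle. The package
    provides the full forward-Euler simulation engine (compiled inner loop),
    calibration routines for a consistent resting state, deterministic spike
    train fixtures, tidy time-series output, broom-style tidiers and ggplot2
    plotting, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
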