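Package: zymokin
Title: Zymogen Activation Kinetics from Fluorimetric Assays and
    Quenched-Flow Electrospray Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify protease-mediated activation of the house
    dust mite zymogen proDer p 3 and its propeptide mutants. Provides
    proteoform bookkeeping (average masses, charge-state m/z, cleavage
    mass balance, N-terminal truncation catalogs, proline-rich motif
    detection), two-state thermal-unfolding fits of fluorescence melting
    curves, lag-phase progress-curve fitting for pseudo-first-order
    activation rate constants, Michaelis-Menten zymogen-depletion models
    (numerical and closed-form), species reaction networks for mutant
    maturation, and quenched-flow electrospray-MS quantification via
    extracted-ion currents, internal-standard normalization, and
    concentration reconstruction. A synthetic-data generator emulates the
    fluorimeter and the mass spectrometer from ground-truth parameters
    for validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
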