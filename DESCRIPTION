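Package: yeastgates
Title: Kinetic Models of Multicellular Yeast Logic Gates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic and stochastic kinetic models of a synthetic
    logic-gate system built from communicating Saccharomyces cerevisiae
    populations. Engineered sender cells secrete alpha-factor pheromone in
    response to chemical inputs (NaCl via the HOG pathway, doxycycline via a
    Tet-Off promoter, galactose via the GAL1 promoter) and reporter cells
    express GFP from a pheromone-responsive promoter. The package couples the
    single-cell ODE models into IDENTITY, NOT, OR, IMPLIES and NAND gates plus
    a three-value gate variant, integrates them with stiff ODE solvers,
    simulates reporter-cell noise with the Gillespie direct method and a
    hybrid deterministic-stochastic scheme, quantifies population noise as
    coefficients of variation, and ranks parameters by finite-difference
    sensitivity of the GFP output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
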