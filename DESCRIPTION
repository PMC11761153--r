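Package: locustdyn
Title: Temperature-Driven Dual-Phase Desert Locust Population Dynamics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stage-structured population model of the desert locust
    (Schistocerca gregaria) with solitarious and gregarious phases in the
    egg, hopper and adult stages, and temperature-dependent vital rates.
    Provides thermal response curves (Gaussian fecundity, Allahyari
    development rates, lethal-window mortality), nonlinear least-squares
    fitting of those curves to temperature-rate tables, autonomous and
    seasonally forced ODE simulation, the basic offspring number via a
    closed form and a next-generation-matrix oracle, equilibria, Jacobian
    stability, transcritical bifurcation coefficients, a periodic (Floquet)
    basic offspring ratio for the forced system, and Latin-hypercube /
    partial-rank-correlation sensitivity analysis.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
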