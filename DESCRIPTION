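Package: satabs
Title: Closed-Form and Numerical Solutions of Saturable Drug-Absorption Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for one-compartment drug-absorption models in which the
    absorption rate saturates with the amount of drug available, as observed
    for carrier-mediated transport. Implements the first-order model, Hill
    kinetics, and a generalized Hill model with decoupled numerator and
    denominator exponents. Provides exact closed-form amount-time solutions
    via the Lambert W and Wright omega functions where the model admits them
    (including Michaelis-Menten kinetics), a guaranteed-convergent implicit
    solver for the general case, an independent adaptive ODE integrator for
    verification, least-squares estimation of absorption parameters from
    amount-time observations, and a command-line interface for simulation,
    comparison, and fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
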