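Package: propgf
Title: Time-Dependent Propagators for Stochastic Gene-Expression Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical evaluation of time-dependent transition probabilities
    (propagators) for two stochastic models of gene expression: an
    autoregulated telegraph model for protein counts, and a two-stage
    telegraph model with explicit mRNA and protein. Probability-generating
    functions are obtained in closed form by the method of characteristics,
    with regular perturbation in a small autoregulation rate and a slow-fast
    singular perturbation in the mRNA/protein decay-rate ratio; propagator
    probabilities are recovered by discretised Cauchy contour integrals
    (equivalently, a discrete Fourier transform of contour samples).
    Finite-state-projection integration of the chemical master equation and
    Gillespie simulation are included as independent oracles, together with a
    transition log-likelihood front end for protein time-series data and a
    synthetic-series generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Matrix,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
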