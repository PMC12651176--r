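Package: amariepr
Title: Entropy Production in the Stochastic Linearized Amari Neural Field Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies irreversibility in spatially extended stochastic
    neural dynamics. Implements the linearized Amari neural field model on a
    periodic one-dimensional lattice with additive, spatially correlated
    Gaussian white noise, and computes its stationary entropy production rate
    by three mutually validating routes: the analytic trace formula built on
    the Lyapunov equation for the stationary covariance, the Lebowitz-Spohn
    path functional evaluated on simulated trajectories with the Stratonovich
    prescription, and the per-Fourier-mode closed form available under
    translational invariance. Also provides detailed-balance diagnostics for
    general drift/noise pairs, the Shannon/reservoir entropy-rate
    decomposition for the stationary Gaussian state, parametric synaptic and
    noise kernel generators, an Euler-Maruyama integrator for the linear
    Langevin dynamics, and a JSON-configured analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
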