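Package: cgion
Title: Stochastic Coarse-Grained Ion Dynamics and Multiscale Coupling to Brownian Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a stochastic coarse-grained (CG) model of an
    ion in aqueous solution, written as a linear system of stochastic differential
    equations for position, velocity, acceleration and one auxiliary variable.
    Includes closed-form parametrization of the four CG coefficients from fine-scale
    moment statistics (diffusion constant and stationary second moments), exact
    linear analysis (drift-matrix eigenvalues, second-moment ODE systems, mean-square
    displacement time shifts, analytic velocity autocorrelation functions),
    coupling of the CG model to large-timestep Brownian dynamics through a nested
    domain decomposition with hand-shaking overlap regions, half-space density and
    first-passage (escape time) experiments, a hierarchy of fictitious-particle
    heat-bath models generalizing the CG model with Lyapunov-equation stationary
    covariances and constrained acceptance-rejection fitting of velocity
    autocorrelation functions, and a surrogate fine-scale trajectory generator with
    an end-to-end parameter-recovery pipeline and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    Matrix,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
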