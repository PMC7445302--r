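Package: rosette
Title: Conformational Size Ratios of Ideal Rosette Polymers
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analytical theory and stochastic simulation of ideal (Gaussian)
    rosette polymers: branched macromolecules with f_c linear arms and f_r
    ring arms grafted to a single core. Computes the mean-square gyration
    radius, the Kirkwood hydrodynamic radius and the universal size ratio
    rho = sqrt(<Rg^2>)/R_H in closed form for arbitrary architecture and
    dimension, cross-checks the closed form against numerically quadratured
    pair-contact integrals, draws exact Gaussian conformations (cumulative
    random walks for open arms, Brownian bridges for rings), runs Langevin
    bead-spring molecular dynamics with harmonic bonds, and extrapolates
    finite-chain estimates of rho to the long-chain limit through a
    correction-to-scaling fit rho(N) = rho_inf * (1 + a * N^(-Delta)).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
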