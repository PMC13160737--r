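Package: srlumen
Title: Intraluminal Calcium Diffusion in the Sarcoplasmic Reticulum
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Finite-volume simulation of nonlinear total-calcium diffusion
    within a single sarcoplasmic reticulum (SR) element of amphibian skeletal
    muscle during excitation-contraction coupling. Total Ca2+ diffuses under
    instantaneous 1:1 calsequestrin buffering (rapid-buffer effective
    diffusion coefficient), with ryanodine-receptor release efflux and SERCA
    influx imposed as Neumann boundary fluxes on a cylindrical SR element.
    Provides the Table-of-constants parameter registry with derived
    geometric and flux quantities, the free/bound/total buffer algebra, 1D
    axial and 2D axisymmetric discretisations, stiff method-of-lines
    integration, analytic and brute-force reference solvers, observable
    extraction (axial and radial profiles, percent declines, end-to-end free
    Ca2+ differences), and a pre-registered simulation condition matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
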