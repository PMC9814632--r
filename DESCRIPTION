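Package: turingforce
Title: Turing Patterns of the Lengyel-Epstein Model Under a Periodically Forced Feed
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and stability analysis of Turing pattern formation in the
    two-variable Lengyel-Epstein activator-inhibitor model of the chlorite-iodide-
    malonic acid (CIMA) reaction when the feed parameter is modulated sinusoidally
    in time. Provides the forced kinetics and their linearization; estimation of the
    dimensionless feed parameters from CIMA rate laws and tank feed concentrations,
    together with a stirred-tank feed-modulation model and pump-program design;
    classical Hopf and Turing bifurcation analysis of the unforced model; Floquet
    stability of the uniform oscillatory state through a linearized Poincare map
    built as an Euler product, including T-A phase diagrams; a 2-D alternating
    direction implicit (ADI) finite-difference reaction-diffusion solver with Heun
    reaction updates, periodic boundaries and staged forcing protocols; and spectral
    pattern classification (spots, stripes, homogeneous states) with wavelength-
    locking checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    png,
    withr
Config/testthat/edition: 3
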