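Package: xbkinetics
Title: Metabolite-Sensitive Three-State Cardiac Cross-Bridge Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for modelling the frequency response of activated cardiac
    muscle with a three-state stiffness-distortion cross-bridge model whose
    transition rates are sensitive to ATP and inorganic phosphate.  Provides
    the nonlinear ODE model, its analytic linearisation to the complex
    modulus (elastic and viscous moduli over a frequency grid), systematic
    enumeration of the 64 strain/metabolite model permutations, particle
    swarm fitting of model permutations to per-condition complex-modulus
    datasets, time-domain validation protocols (sinusoidal perturbation with
    FFT-derived moduli and force-redevelopment simulations), and a synthetic
    data generator that emulates the structure of permeabilised trabecula
    measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    rlang,
    deSolve,
    ggplot2,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
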