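Package: gfchaos
Title: Embedded Dynamics of the Gyorgyi-Field Model of the
    Belousov-Zhabotinsky Reaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and regime classification for the three-variable
    Gyorgyi-Field model of the Belousov-Zhabotinsky reaction in a
    continuous-flow stirred-tank reactor.  Integrates the dimensionless
    kinetic equations with adaptive solvers (compiled right-hand side and
    analytic Jacobian), sweeps the flow-rate parameter, and classifies
    each regime with the 0-1 test for chaos, approximate entropy, the
    Lyapunov spectrum by tangent-space QR re-orthonormalization,
    local-maxima bifurcation diagrams, Poincare sections and Fourier
    amplitude spectra, including nested-interval zooms of the flow-rate
    axis.  Ships a generator of validation signals of known dynamical
    class (harmonic, period-doubled, chaotic map, white noise) so every
    indicator is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
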