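Package: mdbias
Title: Microdialysis Measurement Bias in Interstitial Glucose Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Biophysical models of glucose transport between skeletal-muscle
    capillaries and interstitial fluid, and of the measurement bias that a
    microdialysis probe introduces by continuously removing glucose from the
    tissue it samples. Provides a steady-state three-compartment
    (plasma-endothelium-interstitium) Krogh-cone model predicting the
    unperturbed interstitial glucose concentration from blood flow and
    metabolism, a radial reaction-diffusion model of the concentration field
    around a probe (modified-Helmholtz closed form via Bessel K0, with
    finite-difference and time-dependent solvers), simulated no-net-flux and
    internal-reference recovery calibrations, permeability-surface (PS)
    product calculations, and tools to correct experimental microdialysis
    measurements for the removal bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
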