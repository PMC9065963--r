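Package: urbanpattern
Title: Emergent Urban Patterning from Coupled Population-Service Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of a coupled integro-differential model
    of residential population density and service land fraction on periodic
    domains. Nonlocal interactions enter through Gaussian (and shifted
    Gaussian) spatial weight kernels with analytic Fourier transforms, so
    convolution, linear stability analysis and time integration share one
    spectral representation. The package provides the three model variants
    (conserved-population base model, competition for space with a preferred
    distance to services, and logistic population growth), per-wavenumber
    stability matrices and dispersion relations with in-phase/out-of-phase
    classification, analytic bifurcation and instability conditions,
    pseudo-arclength continuation of patterned steady states with stability
    flags, seeded synthetic field and point-set generators, and dominant
    length-scale estimators (distance-binned Moran correlograms and transect
    power spectra).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
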