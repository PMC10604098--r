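Package: diamondsense
Title: Dual-Modality Nanodiamond Thermometry and Microrheology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for dual-modality nanodiamond
    sensing: optically detected magnetic resonance (ODMR) nanothermometry
    (interpolation shift fitting, Allan-deviation sensitivity, Cramer-Rao
    shot-noise benchmark) and single-particle-tracking nanorheometry
    (time-averaged mean square displacement with analytic variance
    estimates, Stokes-Einstein hydrodynamic radius, Mason generalized
    Stokes-Einstein complex moduli, Welch power-spectral-density
    active-force decomposition, and directed-motion segmentation via the
    directionality ratio). Includes synthetic generators for Brownian,
    fractional Brownian and directed trajectories, ODMR photon-count
    spectrum streams, resistive temperature detector traces, and a
    double-plane orbital-tracking feedback simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
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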