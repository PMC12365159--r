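Package: pestivol
Title: Pesticide Volatilisation Fluxes by Inverse Dispersion Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers pesticide volatilisation fluxes from gas-concentration
    time series measured above a treated field. Implements Monin-Obukhov
    stability corrections and transfer resistances, a semi-analytical
    area-source dispersion model with power-law wind and diffusivity
    profiles, concentration-to-flux inversion and the aerodynamic-gradient
    method, a big-leaf resistance scheme for canopy-surface vapour pressure
    and the surface availability ratio with fitted double-exponential
    dynamics, Monte-Carlo uncertainty propagation to flux percentile bands
    and cumulative-loss bounds, proton-transfer-reaction mass-spectrometry
    calibration utilities (chlorine isotope envelopes, sensitivity, limits
    of detection), application-dose assessment from exposed filters, and a
    synthetic campaign generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
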