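Package: sorptherm
Title: Moisture Sorption Isotherms, Sorption Thermodynamics and Water
    Plasticization for Food Powders
Version: 0.1.0
Authors@R: person("sorptherm", "maintainers", email = "sorptherm@example.org",
    role = c("aut", "cre"))
Description: Tools for the complete moisture-sorption analysis of hygroscopic
    food powders such as fish-gelatin powder. Fits a registry of classical
    sorption isotherm models (Peleg, GAB, BET, Halsey, Oswin, Smith,
    Adam-Shove, modified Oswin, modified Halsey, Dent) per branch and
    temperature by multi-start nonlinear least squares, ranks them by the
    usual R-squared / mean relative percent error / sum-of-squared-error
    criteria, computes Dent-model spreading pressure in closed form validated
    against numerical quadrature, derives net and integral isosteric heats,
    differential entropy and Gibbs free energy from Clausius-Clapeyron
    isosteres, tests enthalpy-entropy compensation against the harmonic mean
    temperature, and fits the Gordon-Taylor glass-transition model to derive
    critical storage conditions. Includes a synthetic-data generator that
    emulates dynamic vapor sorption and differential scanning calorimetry
    measurements so every pipeline stage is testable without instrument data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
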