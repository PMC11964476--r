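Package: hemospec
Title: Fluorescence and Absorption Spectroscopy Toolkit for Hematology
Version: 0.1.0
Authors@R:
    person("Batumi", "Spectroscopy Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of blood fluorescence and absorption
    spectra for hematological diagnostics. Generates synthetic
    excitation-emission matrices (EEMs) from a library of endogenous
    fluorophores (tryptophan, NADH, flavins), hemoglobin absorption spectra
    as a function of oxygenation and glycation, full-range (200-900 nm)
    patient spectra, light-scattering profiles, and complete blood count
    (CBC) records.  Provides the preprocessing chain (maximum-intensity
    normalization, baseline correction, Gaussian smoothing, peak fitting),
    closed-form photophysics (Beer-Lambert quantification, Stokes shift,
    integrated intensity, penetration depth), erythrocyte biophysics
    (shape factor, deformability indices, DLVO interaction energy,
    scattering-based sizing), and a three-band diagnostic comparison of
    patient spectra cross-validated against CBC values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
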