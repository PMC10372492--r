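Package: ripplemetrics
Title: Spectrotemporal Ripple Psychophysics and Objective Measures for
    Cochlear-Implant Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for a model-based cochlear-implant fitting battery:
    synthesis of moving spectrotemporal ripple stimuli and ripple-grid
    experiment designs; simulation and censored maximum-likelihood fitting
    of LATER-model (recinormal) reaction-time distributions with reciprobit
    diagnostics and likelihood-ratio condition comparisons; assembly of
    spectrotemporal modulation transfer functions with cross-sections,
    separability and direction-asymmetry indices; enumeration of nonlinear
    intermodulation distortion products and prediction of (electrically
    evoked) auditory steady-state response target frequencies; spectral
    F-test detection of steady-state components in epoch-averaged EEG-like
    records; and bilinear sound-localization regression under level roving.
    Every analysis is paired with a seeded simulator so the full battery is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
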