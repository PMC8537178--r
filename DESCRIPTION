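Package: hydrospec
Title: Broadband Depolarized Light Scattering and Solute-Correlated
    Infrared Analysis of Protein Hydration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify protein hydration in aqueous
    protein/cosolute mixtures from broadband depolarized light scattering
    susceptibility spectra and ATR-FTIR spectra.  Implements the
    intensity-to-susceptibility conversion through the Bose-Einstein
    occupation factor, analytic susceptibility components (Debye,
    Cole-Davidson, damped harmonic and Brownian oscillators, power law), a
    staged nonlinear least-squares decomposition of binary and ternary
    solution spectra via the difference-spectrum method, hydration-shell
    water counting from relaxation amplitudes, Arrhenius analysis of
    relaxation times, isolation of terahertz vibrational bands, and
    solute-correlated infrared spectrum extraction by constrained spectral
    subtraction.  A synthetic-spectrum generator with known ground truth
    supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
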