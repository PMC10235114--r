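Package: bdsfit
Title: Broadband Dielectric Spectroscopy Analysis of Glass-Forming Liquids
    Under Temperature and Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing broadband dielectric spectroscopy (BDS) data of
    supercooled liquids and glasses at ambient and elevated pressure:
    Havriliak-Negami and Kohlrausch-Williams-Watts lineshape models, spectral
    deconvolution into dc-conductivity plus relaxation processes,
    temperature-pressure superpositioning diagnostics of the structural
    relaxation, fitting of the pressure-extended Avramov equation of state for
    the alpha-relaxation time surface and the derived Tg(p) curve, fractional
    Debye-Stokes-Einstein analysis of conductivity-relaxation coupling,
    Arrhenius/Eyring/activation-volume reductions of secondary (Johari-Goldstein
    type) relaxations, and DSC glass-transition/melting reductions. A
    synthetic-data generator emulating a high-pressure dielectric study of an
    amorphous pharmaceutical makes every stage verifiable against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
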