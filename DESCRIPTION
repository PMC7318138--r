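Package: filmquench
Title: LET Quenching Corrections for Radiochromic Film Dosimetry in Proton Beams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and correct the linear-energy-transfer (LET)
    quenching of radiochromic (EBT3-type) film response in proton beams. The
    package implements the bimolecular net-optical-density calibration model
    with an LET-dependent half-saturation dose, a spectrum-resolved
    net-optical-density integrator over proton fluence distributions
    differential in LET, inverse optimisation of the LET dependence from
    measured beam-quality correction factors, a practical dose-averaged-LET
    (Ld) polynomial corrector, and an analytic primary-proton beam simulator
    (Bragg curves, spread-out Bragg peak composition, LET spectra and
    dose/fluence-averaged LET depth profiles) for fully synthetic end-to-end
    studies. An embedded ICRU49/PSTAR-consistent proton stopping-power table
    for liquid water underpins both the simulator and the quench model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    pracma,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
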