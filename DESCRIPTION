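Package: borondose
Title: Boron-Based Dose Enhancement Analysis for Proton Therapy
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analytic pipeline comparing two boron-mediated dose-enhancement
    schemes in proton therapy: proton-boron fusion (P-BFT, via 11B(p,aa)a) and
    neutron-capture enhancement (NCEPT, via 10B(n,a)7Li). Provides a
    Bragg-Kleeman range-energy model with spread-out Bragg peak construction,
    deterministic in-tumor proton slowing-down spectra, calibrated three-group
    secondary-neutron spectra, cross-section table I/O with multigroup
    collapse, an Eq.-style flux-cross-section folding engine for reaction
    rates, equivalent-dose conversions (quality factors, ICRP-21 flux-to-dose
    factors, radiation weighting factors), a thermal-neutron absorption
    competition estimator, and a scenario driver with a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
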