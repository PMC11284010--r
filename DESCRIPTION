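Package: coromix
Title: Mixing Assessment for Coronary Infusion Catheters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative assessment of saline-blood mixing by coronary
    infusion catheters used for continuous-infusion thermodilution. Provides
    a desk-scale pulsatile advection-diffusion simulator of scalar (thermal)
    transport in a catheterised coronary artery for side-hole and end-hole
    injection topologies, cross-section mixing statistics (time-averaged
    standard deviation and Shannon-entropy ratio), pullback temperature
    deviation analysis with exceedance fractions, and a projectional
    uniformity classifier with pass/fail contingency tabulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml,
    zoo
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
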