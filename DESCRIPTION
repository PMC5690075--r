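Package: oculardose
Title: Proton Pencil-Beam Dose Simulation for Ocular Treatments on a
    Scanned Beamline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation of an actively scanned proton beamline
    adapted for uveal-melanoma treatment: a power-law range-energy model
    calibrated on published synchrotron data, analytic Bragg curves with
    range straggling, moment-based (Fermi-Eyges) transverse beam transport
    through the monitor-chamber foil stacks and a PMMA range shifter,
    spread-out Bragg peak weight optimisation, scanned-spot delivery with a
    brass collimator onto water boxes, a parameterised anatomical eye
    phantom or a synthetic CT series, and dose scoring (FWHM, 80-20%
    penumbra, plateau uniformity, SOBP width and falloff, per-structure
    dose-volume histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
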