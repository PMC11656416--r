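Package: gradpka
Title: pKa and Concentration of NMR-Invisible Acids from pH-Gradient NMR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Determines the acid dissociation constant (pKa) and total
    concentration of acidic species that need never be observed directly by
    NMR. A basic indicator diffuses along a tube, and each slice of a
    chemical shift imaging (CSI) experiment yields the local pH (from the
    indicator chemical shift, with a Davies-type ionic-strength correction)
    and the concentration of protons transferred from the analyte (kappa,
    from the indicator integral and the free-proton term). A linear plot of
    1/kappa against 10^-pH then gives pKa and the analyte concentration with
    95% confidence intervals; a nonlinear route cross-checks the linear one.
    Includes an exact acid-base speciation solver used as an internal oracle,
    a forward simulator of the whole gradient experiment (diffusion profile,
    per-slice equilibria, measurement noise), limiting-shift calibration
    against a strong-acid gradient, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    optparse,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
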