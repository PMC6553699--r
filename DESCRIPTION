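Package: wsshisto
Title: Registration of Wall Shear Stress Maps to Serial Histology of Carotid Plaques
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to bring in vivo MRI, ex vivo MRI, en-face block photographs and
    serial histology of excised carotid plaques into one shared image domain, and to
    project lumen wall shear stress (WSS) maps onto histological cross-sections.
    Implements landmark-based similarity registration, contour-driven B-spline
    free-form deformation, maximally-inscribed-circle vessel centerlines, radial
    binning of WSS and plaque thickness, Dice/Hausdorff registration quality control
    with error-type exclusion bookkeeping, and an axial registration-mismatch
    sensitivity simulation with Wilcoxon and Pearson statistics. Ships a synthetic
    phantom generator with known ground-truth transforms and analytic per-bin WSS so
    the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deldir,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
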