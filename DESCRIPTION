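Package: hingefit
Title: Mandibular Hinge-Axis Registration from Dual-Bite Intraoral Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the mandibular axis of rotation (hinge axis) from
    corresponded triangle meshes of a dental arch captured in closed- and
    open-bite poses, and validates the fitted axes against replicate
    reference axes from jaw motion tracking. Provides rigid-body and
    screw-axis geometry, a two-stage rotation-only least-squares axis fit,
    corresponded-mesh deviation metrics with the 0.1 mm clinical threshold,
    the EcD (error-caused displacement) and AEcFE (axis error caused final
    error) propagation ratios, virtual-articulator simulation setups,
    an axis-error direction sensitivity scan, and a seeded synthetic
    generator of dual-bite scan sessions with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
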