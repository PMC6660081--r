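Package: scleratopo
Title: Artefact-Free Corneoscleral Topography and Scleral Asymmetry
Version: 0.1.0
Authors@R: person("Scleratopo", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Processing pipeline for anterior-eye elevation point clouds from
    corneoscleral topographers. Detects the limbus per meridian from the
    second derivative of raw elevation, levels the surface about the
    least-squares limbus plane, removes peripheral edge-effect artefacts
    (lid lift-off, tear pooling, lash spikes) with a robust moving-median
    slope screen, fits a best-fit reference sphere to the scleral annulus to
    obtain relative elevation maps, and quantifies scleral asymmetry per
    meridian with two-sample t-tests. Includes a synthetic-eye generator
    with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
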