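Package: ulmpipe
Title: Ultrasound Localization Microscopy Pipeline for Contrast-Enhanced
    Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction and quantification of super-resolved
    microvascular maps from contrast-enhanced ultrasound (CEUS) clips by
    ultrasound localization microscopy (ULM): spatiotemporal singular-value
    clutter filtering, radial-symmetry sub-pixel microbubble localization,
    gated optimal-assignment track linking, accumulation of density,
    directivity and velocity maps on an upsampled grid, per-track shape
    metrics (velocity, dispersity, tortuosity, distance metric), region-wise
    and percentile flow summaries, and lognormal bolus time-intensity-curve
    kinetics. Includes a ground-truthed synthetic microbubble-flow phantom
    generator so the whole pipeline can be exercised and validated without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
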