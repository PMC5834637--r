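Package: pengcensus
Title: Multi-Modal Census of Penguin Mega-Colonies from UAV and Satellite Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for censusing colonially nesting seabirds
    from aerial imagery. Simulates colony layouts as clustered hard-core point
    processes and renders orthomosaic-like rasters with confusable artifacts;
    detects candidate nests with a tiled difference-of-Gaussians blob detector;
    removes spatially unstructured false positives with a nearest-neighbour
    filter; implements the triple-count ground protocol with N1/N2/N4 precision
    classes; calibrates automated counts against validation counts by
    site-specific linear regression; propagates per-island precision classes to
    an archipelago-wide 95% confidence interval by Monte Carlo; and
    cross-calibrates multispectral scenes by per-band mean differences for
    guano-area change comparison on a 30 m grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    withr,
    mgcv,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
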