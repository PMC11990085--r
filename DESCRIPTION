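Package: stitchflat
Title: Vignetting Correction for Stitched Tile-Mosaic Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Corrects vignetting (shading) artifacts directly on fully
    stitched tile-mosaic grayscale microscopy images, without access to the
    individual tiles. Tissue is separated from background by morphological
    texture filtering, the tile period is recovered from the frequency
    spectrum of the mean intensity profiles, and per-axis correction
    multipliers are derived from smoothed envelopes of those profiles.
    An optional morphological top-hat refinement stage flattens residual
    shading. Includes a ground-truthed simulator of vignetted particle
    mosaics and evaluation metrics (profile flatness, particle detection,
    per-tile density maps, RMSE and Pearson correlation against ground
    truth).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    tiff,
    jsonlite,
    mclust,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
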