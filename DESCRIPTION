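Package: clemux
Title: Demultiplexing Combinatorial Fluorescent Barcodes in Correlative
    Light-Electron Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for multiplexed correlative light and electron microscopy
    (CLEM) of pooled, combinatorially barcoded cell populations. Detects cell
    profiles in medium-magnification EM overviews by watershed segmentation of
    a pixel-class map, registers the light-microscopy frame to the EM frame
    with a landmark affine fit, measures per-cell median fluorescence through
    dilated, overlap-subtracted masks, demultiplexes binary fluorophore
    barcodes by two-step intensity normalization and k-means clustering, and
    exports selected cell coordinates to SerialEM Navigator (autodoc) files
    for automated high-resolution acquisition. Includes stereological
    organelle morphometry (Delesse volume fraction with a ratio-estimator
    standard error, surface-to-volume from profile areas and circumferences)
    and a ground-truthed synthetic-data generator so the whole pipeline is
    testable without a microscope.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
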