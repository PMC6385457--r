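Package: spotmark
Title: Optical Mark Recognition Cards for Field Photography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design, render and decode reusable annotation cards
    ("spot cards") for field photography of plants. One half of the
    package lays out printable cards carrying category spot grids and
    four colored fiducial corner dots; the other half batch-processes
    photographs to locate and orient the card, validate its geometry,
    read the inked spots, extract EXIF date/time/GPS, and measure the
    photographed flower's area and perimeter in millimetres using the
    card's known physical size as the scale reference. A synthetic
    fixture renderer produces ground-truth photographs (rotation,
    out-of-plane tilt, noise, injected EXIF) so the whole pipeline is
    testable without any real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jpeg,
    png,
    tiff,
    jsonlite,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
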