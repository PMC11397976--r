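Package: canopyscope
Title: Automated Multispectral Canopy Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Automated analysis of co-registered multispectral plant images
    for controlled-environment phenotyping. Segments the plant canopy from
    the background using a chlorophyll-fluorescence image (automatic valley
    thresholding between the two leftmost histogram peaks, with size-based
    despeckling), quantifies projected canopy area in square centimeters,
    computes masked normalized-difference index images (NDVI, NDAI and
    user-defined band pairs) with per-canopy statistics, histograms and
    false-color renderings, batch-processes folders of image sets to CSV,
    automates gray-card exposure calibration, and generates synthetic
    multispectral scenes with exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
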