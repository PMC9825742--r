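Package: dropcall
Title: Model-Based Droplet Calling and Methylation Normalization for Droplet Digital PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated per-well, per-channel thresholding of droplet digital
    PCR (ddPCR) fluorescence amplitudes using Gaussian mixture models with
    robust removal of destroyed droplets, Poisson-based absolute
    quantification with Wilson-score confidence intervals, and normalization
    of DNA methylation levels against a single-gene or four-gene (4Plex)
    internal control. Reads per-well amplitude CSV files as exported by the
    Bio-Rad QX ddPCR system together with an optional QuantaSoft-style sample
    sheet, writes a per-plate results table and per-well droplet label
    exports, and supports manual threshold override with re-quantification.
    A plate simulator with known ground truth (negative/positive clouds,
    rain, destroyed droplets, baseline shifts) makes the whole workflow
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    mclust,
    jsonlite,
    ggplot2,
    patchwork,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
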