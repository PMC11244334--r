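Package: adipotrace
Title: Quantification of Adipocyte Lineage-Tracing Microscopy and Culture
    Composition Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for fluorescence-reporter lineage tracing of
    adipocyte dedifferentiation cultures. Simulates multi-channel reporter
    microscopy fields (nuclear counterstain, nuclear or membrane GFP/tdTomato,
    and a proliferation marker such as EdU or phospho-histone H3) with exact
    ground truth; segments nuclei from the counterstain by smoothing,
    thresholding and distance-transform watershed; measures per-nucleus mean
    GFP/RFP and integrated marker signal; gates cells by a fixed GFP/Tomato
    ratio cutoff and marker cutoff; summarises per-well fractions with
    replicate statistics (mean, SEM, Student t tests); and implements a
    discrete-time cell-population composition model that quantifies how a
    small contaminating proliferative population overgrows non-dividing
    adipocyte-derived cells as a function of doubling time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
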