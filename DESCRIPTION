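Package: netmorph
Title: Quantification of NETosis from Nuclear Morphology, cfDNA and
    Bacterial-Killing Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation-backed pipeline for quantifying neutrophil
    extracellular trap (NET) formation. Generates synthetic populations of
    Sytox-stained neutrophil nuclei in the four NETosis stages (lobulated,
    delobulated, diffused NETs, spread NETs) with ground truth, segments
    nuclei from single-channel fluorescence images, extracts morphometric
    features including the Heywood circularity factor, trains and applies a
    random-forest nuclear-morphology classifier, aggregates per-cell calls
    into per-donor stage distributions, and quantifies companion plate
    assays (Sytox-green cfDNA standard curves and CFU-based bacterial
    killing percentages).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    randomForest,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
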