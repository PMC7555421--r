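Package: elamap
Title: Elemental Bioimaging by Laser Ablation ICP-MS Line Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs calibrated multi-element concentration maps of
    tissue sections from laser ablation inductively coupled plasma mass
    spectrometry (LA-ICP-MS) line scans. Provides a synthetic-data
    generator for liver-section phantoms and an instrument model, raw-run
    and map input/output, line-scan image assembly with background
    subtraction and carbon-13 internal-standard normalization,
    matrix-matched external calibration with limit-of-detection
    estimation, tissue segmentation, per-element quantification reports
    with a hepatic-copper diagnostic rule, and false-color map rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
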