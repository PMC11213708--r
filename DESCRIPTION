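Package: flimstain
Title: Virtual H&E Staining and Quantitative Analysis of Fluorescence
    Lifetime Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Converts fluorescence lifetime imaging microscopy (FLIM)
    exports into network-ready stain-translation inputs (greyscale
    intensity, alpha-FLIM and intensity-weighted FLIM), co-registers them
    with bright-field H&E images, trains a conditional adversarial
    image-to-image translation model under a combined adversarial, L1 and
    deep structure/texture similarity (DISTS) objective, scores virtual
    against true staining with standard similarity metrics (NRMSE, NMI,
    PSNR, MSSIM), and extracts per-cell lifetime signatures from
    annotation masks. A deterministic tissue-phantom generator provides
    paired synthetic data so the whole pipeline runs end to end without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
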