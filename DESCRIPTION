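Package: cycloplex
Title: Cyclic Multiplex Immunofluorescence Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated workflow for cyclic multiplex immunofluorescence
    microscopy of tissue sections: per-channel background and
    autofluorescence subtraction, collagen extraction from trichrome RGB,
    DAPI-anchored affine registration of staining cycles, trainable pixel
    classification and nucleus segmentation, per-cell marker gating into
    phenotypes (e.g. Kupffer cells versus monocyte-derived macrophages),
    and spatial analytics including density maps, dilation-based neighbor
    counting and collagen/PCNA-based tumor-region delineation. Ships a
    synthetic-tissue renderer with full ground truth so that every stage
    of the pipeline can be validated by ground-truth recovery.
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
    ranger,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
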