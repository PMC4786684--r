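Package: gliaquant
Title: Quantification of Microglial Dynamics in Time-Lapse and Fixed-Tissue Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-quantification toolkit for microglial dynamics during
    ocular dominance plasticity: Sholl ramification profiles on binarized
    arbors, pixel-classification motility / extension / retraction and
    stability indices from registered time-lapse projections, laser-ablation
    chemotaxis response curves R(t), triangle auto-thresholding with
    two-channel puncta engulfment scoring, stimulus-locked Fourier amplitude
    maps with an ocular dominance index, and area-normalized electron
    microscopy event statistics with one-pass Grubbs outlier removal. A
    seeded synthetic-data generator produces ground-truthed inputs for every
    stage so the whole pipeline is verifiable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
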