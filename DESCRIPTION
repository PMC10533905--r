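Package: matriscope
Title: Collagen Texture, Basal-Cell Migration and Matrisome Analytics for
    Fibrotic Lung Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analyses of fibrotic extracellular matrix and
    KRT5+ airway basal cell behaviour: regional collagen-organisation scoring
    of 2D greyscale images (collagen density, grey-level co-occurrence matrix
    texture features, structure-tensor fibre coherency), single-cell migration
    analytics (track filtering, speed, straightness ratio, mean squared
    displacement, persistent-random-walk fitting, motility classification),
    the delta-delta-CT relative qPCR expression workflow, and differential
    matrisome protein-abundance statistics with Benjamini-Hochberg control.
    A synthetic-data generator produces ground-truthed fibrous images, cell
    tracks, CT plates and abundance tables so every stage is testable without
    microscopy or proteomics downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
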