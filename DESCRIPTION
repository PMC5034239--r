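Package: fadyn
Title: Quantification of Focal Adhesion Turnover and Peripheral Trafficking
    from Fluorescence Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-quantification toolkit for focal adhesion (FA) dynamics
    at the edge of migrating cells. Builds kymographs along each adhesion's
    growth axis and estimates assembly and disassembly rates, halt time and
    lifespan from half-maximum tip tracking; computes differential triple
    colocalization by exclusive binary-mask algebra with integrated
    densities in neighbourhoods around reference adhesions; partitions the
    cell footprint into a peripheral band and a central region by Euclidean
    distance from the cell edge and derives enrichment statistics for
    vesicle and adhesion markers; and measures cell morphometrics
    (projected area, circularity, aspect ratio). A seeded synthetic
    time-lapse simulator with full ground truth (adhesion kinetics,
    vesicle placement bias, prescribed exclusive channel overlaps) makes
    every stage testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    grDevices,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
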