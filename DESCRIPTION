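Package: ccfd
Title: Choriocapillaris Flow Deficit Quantification from En-Face OCTA Slabs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies choriocapillaris flow deficits on co-registered
    en-face optical coherence tomography angiography (OCTA) slab pairs.
    Implements the standard shadow-compensation chain (invert the structure
    slab, Gaussian smoothing, pixelwise multiplication into the flow slab),
    Phansalkar local adaptive thresholding at configurable window radii,
    and connected-component flow-deficit metrics (percentage, count, mean
    size, total area) on a calibrated physical scan geometry. Includes a
    synthetic flow/structure image generator with known ground truth for
    validation, and cohort-level nonparametric and regression statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    png,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    EBImage,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
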