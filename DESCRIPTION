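Package: celldecomp
Title: Iterative Generative Decomposition of Fluorescence Micrographs
    into Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instance segmentation of fluorescence microscopy images by
    analysis-by-synthesis. A vector-quantized variational autoencoder
    (VQ-VAE) is trained to reconstruct only the cell touching the centre
    of an image patch; at inference an internal predicted image is grown
    by repeatedly proposing single-cell reconstructions at maxima of the
    error image (input minus internal image) and keeping only proposals
    that reduce the global L1 discrepancy. Multiple passes over the
    residual error recover cells missed earlier. Includes a synthetic
    micrograph generator with ground-truth label maps, an oracle
    predictor for engine testing, conversion of accepted object images
    to instance label maps, and average-precision evaluation at IoU
    thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tiff,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
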