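Package: embryoflow
Title: Spectral Motion Phenotyping of Embryos from Sparse Optic Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies embryonic movement patterns from grayscale image
    sequences. Sparse optic flow (Shi-Tomasi corner features tracked with
    pyramidal Lucas-Kanade, with velocity-variance rejection) is decomposed
    into four per-frame motion parameters: mean clockwise and anti-clockwise
    rotation angles about the tracked-feature centroid and the polar
    (rho, theta) displacement of the centroid itself. Each parameter series
    is converted to binned spectral energies with the Discrete Fourier
    Transform over period-range bins, and individuals are compared with
    Bray-Curtis dissimilarity, non-metric multidimensional scaling, and
    ANOSIM permutation tests (exact enumeration for small designs). A
    synthetic-data module generates textured rotating embryo-like videos and
    motion time series with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    vegan,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
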