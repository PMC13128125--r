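Package: lumispat
Title: Micro-Scale Spatial Statistics for Gut Microbiota Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies micro-scale clustering of bacteria in gut content.
    Provides cell detection for fluorescence microscopy images (top-hat
    filtering, mean-relative thresholding, morphological region filters,
    food-particle removal and cluster splitting), inhomogeneous Ripley
    K/L/H spatial summary functions with border correction and ratio
    pooling, a Studentized permutation test between groups of point
    patterns, Jensen-Shannon divergence comparisons of community
    profiles, yield-stress estimation from oscillatory amplitude sweeps
    and creep tests, and a Stokes-second-problem model of the mixing
    depth generated by gut-wall contractions. A synthetic-data module
    generates point patterns, images, rheology curves and abundance
    tables with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite
Config/testthat/edition: 3
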