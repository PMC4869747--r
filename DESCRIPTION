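Package: fibermech
Title: Stress-Fiber Quantification and AFM Cell Stiffness with
    Bottom-Effect Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies the amount and architecture of actomyosin stress
    fibers from live-cell epifluorescence images and extracts Young's
    modulus from atomic force microscopy (AFM) force-indentation curves
    using a bottom-effect cone correction for thin samples on rigid
    substrates.  Fiber segmentation uses a rotated bank of elongated
    Laplace-of-Gaussian kernels followed by coherence-enhancing diffusion
    filtering and orientation-consistency trimming; unbound-GFP background
    is removed by masked median filtering.  Per-cell descriptors (fiber
    alignment, apparent fiber thickness, radial location, filamentous
    fraction) are correlated with stiffness through linear models, an
    analysis of covariance, and a normalized architecture-modulation
    model with F-test model selection.  Fully synthetic image and force
    curve generators with ground truth make every stage testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
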