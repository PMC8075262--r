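Package: popcoding
Title: Efficient Population Coding with Input and Output Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Exact mutual-information computation for small populations of
    binary and sigmoidal neurons whose responses are corrupted by additive
    input noise (Gaussian or generalized-normal) before a thresholding
    nonlinearity and by Poisson spike-generation noise after it. Supports
    two readout schemes: an independent-coding channel (the vector of
    per-neuron spike counts) and a lumped-coding channel (the summed spike
    count). Provides information-maximizing threshold optimization,
    noise-plane scans, bifurcation detection with phase-transition
    classification and critical-exponent fitting from the curvature of the
    information landscape, and an application to auditory-nerve-fiber-style
    rate-intensity curves (sigmoid fitting, fiber-type classification,
    information landscapes and information-per-spike analysis), together
    with a synthetic tuning-curve cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    MASS
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
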