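Package: edofscope
Title: Wavefront-Coded Extended Depth-of-Field Microscope Simulation and
    Restoration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a wavefront-coded, extended depth-of-field
    miniaturized microscope. Simulates coded and uncoded point spread functions
    and modulation transfer functions with a Fourier-optics pupil model, selects
    the cubic-phase modulation strength by a Fisher-information merit under a
    Nyquist-MTF constraint, represents shift-variant blur by a low-rank
    non-negative factorization of a field-sampled PSF grid (HALS-NMF with
    channel-uniform coefficients), generates simulation-supervised training
    pairs from synthetic focal stacks (depth fusion to all-in-focus labels,
    physical propagation to coded captures), and restores images by
    TV-regularized ADMM and shift-variant Richardson-Lucy deconvolution.
    Includes layer-graph descriptions with exact parameter accounting for the
    restoration network family and a toy pure-R trainer.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
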