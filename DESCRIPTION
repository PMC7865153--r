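Package: descrambler
Title: Descrambler-Group Interpretation of Fredholm Solver Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interprets small fully connected neural networks that invert
    Fredholm integrals of the first kind, using orthogonal descrambling
    transformations optimized over SO(d) via the Cayley parameterization of
    antisymmetric generators. Ships the complete workflow for the double
    electron-electron resonance (DEER) distance inversion problem: dipolar
    kernel construction from Fresnel integrals, synthetic trace generation
    with baseline, modulation depth and noise, network training, Lie-group
    descrambling with analytic gradients, frequency-domain and singular value
    diagnostics, and a rational digital signal-processing replica built from
    FIR filters and a regularized time-distance transform selected by the
    L-curve method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
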