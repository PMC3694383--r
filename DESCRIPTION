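Package: mritex
Title: Generalized First- and Second-Order Statistical Texture Operators for Grayscale Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for window-based texture analysis of 2-D grayscale
    (MRI-style) images. Implements generalized gray-level histogram moments
    and six generalized co-occurrence operators (homogeneity, contrast,
    inverse difference, entropy, correlation, difference entropy) computed
    on an all-directions "discrete circumference" co-occurrence matrix,
    recognition-window feature maps with image-pyramid support, a supervised
    interval-based texture model with dependence-weighted voting for
    segmentation, a seeded synthetic phantom generator with ground-truth
    labels, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
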