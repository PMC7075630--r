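Package: texstab
Title: Exposure Stability of Haralick Texture Features in PET Phantom Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies how first-order and Haralick (grey-level co-occurrence
    matrix) texture features of PET images depend on exposure, the product of
    activity concentration and acquisition duration. Simulates homogeneous
    cylindrical phantom volumes of interest under reconstruction-dependent
    noise models (Gaussian for filtered back-projection; gamma or log-normal
    for iterative OSEM/PSF reconstructions), computes texture features under
    several grey-level quantization schemes, smooths feature-versus-exposure
    curves with a fixed-window local regression on log-log axes, and detects
    the exposure domains where feature values are stable: plateau onsets,
    islands of stability, and variability ranges in Bel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    RNifti,
    stats,
    utils
Suggests:
    nortest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
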