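Package: dediffract
Title: De-Diffraction of Semi-Annular Laser Autofocus Spot Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for cleaning and measuring semi-annular laser spot images
    produced by multilayer autofocus microscopes. Implements local-mean
    background screening to locate spot intervals, per-row gradient
    run-length classification that separates semi-annular main-spot pixels
    from diffraction speckle, ring-geometry corrections based on the
    proportionality of inner radius and ring width to defocus distance,
    spot beautification and missing-ring reconstruction, and a synthetic
    scene generator with ground-truth masks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
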