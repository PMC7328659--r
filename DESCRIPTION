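Package: fernmask
Title: Segmentation Masks for Digitized Herbarium Specimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for producing binary plant-tissue masks from
    digitized herbarium sheet images. Provides automatic preliminary mask
    generation by Otsu thresholding, mask post-processing (re-binarization and
    neighborhood despeckling with a kernel sweep), a pure-R encoder-decoder
    (U-Net-style) convolutional network for binary semantic segmentation trained
    under a one-cycle learning-rate policy with paired image/mask augmentation,
    Sorensen-Dice and pixel-accuracy evaluation with per-family reporting, and a
    seeded generator of synthetic herbarium sheets with pixel-perfect ground
    truth so the whole pipeline is testable without any image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jpeg,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
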