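Package: plnet
Title: Progressive-Learning U-Net for 2D Medical Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds, trains and evaluates PL-Net, a U-Net variant for 2D
    medical image segmentation that traverses a shared encoder-decoder in
    several internal "steps" linked by forward and backward skip
    connections, and trains in two external "stages" (coarse then fine)
    whose pre-activation outputs are fused with equal weight. Includes the
    preprocessing used for dermoscopy images (gray-world color constancy,
    resizing), geometric training augmentation, synthetic lesion, nuclei
    and cardiac-ring fixture generators, Dice-loss training with early
    stopping, the standard segmentation metric suite (accuracy, IoU, Dice,
    sensitivity, specificity), and a command-line entry point. All network
    numerics (convolution, batch normalization, pooling, transposed
    convolution, reverse-mode differentiation, Adam) are implemented in
    base R on top of BLAS matrix products.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jpeg,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
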