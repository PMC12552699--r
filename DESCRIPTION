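Package: fastdenoise
Title: Self-Supervised Real-Time Denoising of Fluorescence Imaging Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Self-supervised denoising for high-speed fluorescence
    neural imaging (calcium and voltage time-lapse stacks). Training
    pairs are built by frame-multiplexed spatiotemporal sampling:
    temporal sliding windows paired at a shift step, each split into two
    half-resolution views by seeded 2x2 mask-cell subsampling. An
    ultra-lightweight grouped-convolution encoder-decoder (under 0.013
    million parameters) is fitted with a two-part objective combining a
    scale self-constraining term and a spatiotemporal self-supervising
    term with a patch-mean intensity penalty. Includes sliding-window
    and streaming FIFO inference, a mixed Poisson-Gaussian simulation
    harness for calcium and voltage dynamics, trace extraction
    (delta-F-over-F) and fidelity metrics (PSNR, SSIM, Pearson
    correlation), multi-page TIFF input/output, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tiff,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
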