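Package: morphovae
Title: Unsupervised Latent-Space Analysis of Nanoparticle-Induced Cell
    Morphology Change
Version: 0.1.0
Authors@R:
    person("Morphovae", "Developers", email = "morphovae@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting and localizing
    treatment-induced morphological change in two-group single-cell
    image collections (e.g. control versus nanoparticle-treated
    macrophages imaged by phase-contrast microscopy). Images are
    preprocessed (grayscale, contrast-limited adaptive histogram
    equalization, sharpening, resizing, min-max normalization), encoded
    by variational autoencoders (beta-VAE, beta-TCVAE with the mutual
    information / total correlation / dimension-wise KL decomposition,
    and a multi-encoder VAE over augmented views), and the latent
    dimensions are screened by Cohen's d effect sizes with confidence
    intervals, compared by kernel density estimation and violin
    summaries, and interpreted by latent traversals with absolute and
    SSIM-based difference maps. A synthetic two-group cell-image
    generator with analytically known effect sizes makes the whole
    pipeline testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
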