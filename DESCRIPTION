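Package: qipr
Title: Quantitative Image Properties for Empirical Aesthetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the quantitative image properties (QIPs) used in
    empirical aesthetics and visual perception research: image dimensions,
    RMS contrast, lightness and color-channel statistics, Shannon entropies,
    perceptual balance and mirror-symmetry scores, HOG-based complexity,
    anisotropy and PHOG self-similarity, Gabor edge density and first- and
    second-order edge-orientation entropy, Fourier amplitude- and
    power-spectrum slopes and sigma, 2D and 3D box-counting fractal
    dimensions, and variance statistics of first-layer convolutional
    filter responses. Includes deterministic synthetic-image generators
    (random-phase images, fractional Brownian surfaces, line patterns,
    mirrored composites) whose known ground truth exercises every measure,
    and a batch runner that writes one CSV row of measures per image.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    withr
Config/testthat/edition: 3
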