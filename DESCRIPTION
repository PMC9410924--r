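Package: speckleseg
Title: Speckle Simulation, Anisotropic Diffusion and Active-Contour
    Segmentation for Ultrasound Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for segmenting B-mode ultrasound-like images with known
    speckle statistics. Provides a synthetic phantom generator with
    Rayleigh-envelope multiplicative speckle, Perona-Malik anisotropic
    diffusion denoising (optionally homomorphic, in the log domain), a
    pulse-coupled neural network (PCNN) for initial contour extraction, a
    classical parametric active contour (Snake) with semi-implicit
    evolution, a cloud-model differential-evolution refinement of the Snake
    energy, and segmentation/denoising quality metrics (DSC, MCC, pixel
    error rate, PSNR, MSE) with a paired phantom benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
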