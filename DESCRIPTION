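Package: octreg3d
Title: Motion Correction, Registration and Averaging of Volumetric OCT Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A system-agnostic toolkit for registering and averaging serially
    acquired optical coherence tomography (OCT/OCTA) volumes corrupted by eye
    motion. Implements phase-only correlation (POC) shift estimation,
    quality-based reference selection, intra- and inter-volume axial alignment,
    automatic microsaccade detection and removal, coarse-to-fine B-scan
    registration with tolerance-based outlier rejection, strip-wise affine
    rotation correction, multi-volume averaging, and quantitative evaluation
    (MSE, SSIM, multi-scale SSIM, CNR). Ships a synthetic retina-like phantom
    generator with ground-truth motion traces so the full pipeline can be
    validated by parameter recovery, and a command-line interface for batch
    runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
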