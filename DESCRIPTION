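Package: mmpsos
Title: Multiobjective Particle-Swarm Multilevel Thresholding with
    Superpixel Fusion for Histopathology Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and segments regions of interest (typically nuclei) in
    H&E-stained histopathology images by combining multiobjective particle
    swarm optimisation (MOPSO) over three multilevel-thresholding criteria
    (Otsu between-class variance, Kapur entropy, Renyi entropy) with a
    SLIC-style superpixel clustering stage. The swarm maintains an external
    Pareto archive with an adaptive hypercube grid for leader selection; the
    best archive member supplies two intensity thresholds, the darkest
    threshold class is fused with intensity-refined superpixels, and the
    merged mask is cleaned by morphological post-processing. Includes
    pixel- and centre-level evaluation metrics and a synthetic
    histology-fixture generator with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    stats,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
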