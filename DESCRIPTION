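Package: trabsep
Title: Trabecular and Cortical Bone Separation for Micro-CT Volumes
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Semi-automated separation of trabecular from cortical bone in
    three-dimensional micro-CT scans.  From a binary marrow-space mask the
    package reconstructs the trabecular compartment by morphological
    smoothing (ball opening), shrink-wrapping the marrow over the trabeculae
    (large-radius ball closing), a second smoothing pass, and subtraction of
    the eroded marrow space, followed by intersection with the bone
    threshold.  Includes scan preprocessing (edge-preserving denoising,
    greyscale range thresholding, seeded watershed region isolation),
    foramen detection and sealing as mask arithmetic, resolution-aware
    parameter scaling with box-filter downsampling, outcome metrics
    (trabecular BV/TV, trabecular/cortical volume ratio, mean-intercept-length
    degree of anisotropy, intersection over union), a synthetic bone phantom
    generator with ground truth, and multi-page TIFF / NRRD volume I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
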