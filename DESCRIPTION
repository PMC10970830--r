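Package: cytofocus
Title: Frequency-Domain Sharpness Assessment and Restoration Benchmarking
    for Cytology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quality control of stained-cytology micrographs
    affected by microscope defocus. Implements a no-reference sharpness
    metric based on ring-shaped binning of the centered two-dimensional
    discrete Fourier spectrum, full-reference quality metrics (PSNR, SSIM),
    simulators for the distortions that arise during slide digitisation
    (decimation-interpolation cycles, Gaussian and disk defocus,
    illumination presets), classical upsamplers, a calibrated focus gate
    that routes images to pass-through or enhancement, a lightweight
    COCO-style instance-segmentation average-precision evaluator with
    percent-change accounting against a baseline, and a seeded generator of
    cytology-like scenes with exact ground-truth masks for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    png,
    tiff,
    jpeg,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'image_io.R'
    'ring_spectrum.R'
    'degrade_restore.R'
    'synth_cyto.R'
    'quality_metrics.R'
    'seg_eval.R'
    'focus_gate.R'
    'cli.R'
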