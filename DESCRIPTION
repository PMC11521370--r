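Package: foveolar
Title: Foveolar Cone-Mosaic Sampling, Ocular Drift Metrics, and
    Adaptive-Optics Micro-Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cell-resolved visual sampling in the human
    foveola. Computes pixel-resolved cone-density maps from labelled cone
    mosaics via Voronoi tessellation (peak cone density, cone density
    centroid, inter-cone distance, Nyquist limit), models diffraction-limited
    retinal images of Snellen-E optotypes and Gaussian cone light-capture
    apertures to derive per-frame cone activation and sampling cone density,
    quantifies fixational ocular drift (path length, landmark-relative
    directionality, tuning ratio, Rayleigh test, isoline areas, convergence,
    sampling gain), and estimates 4AFC acuity thresholds with QUEST adaptive
    staircases and maximum-likelihood psychometric fits. Includes synthetic
    generators for cone mosaics, drift traces, and full psychophysical
    sessions with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deldir,
    RANN,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
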