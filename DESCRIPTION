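Package: retmorph
Title: Automated Retinal Vascular Morphometry from Fundus Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fully automated quantitative measurement of retinal vascular
    morphology on optic-disc-centred fundus photographs. Implements the
    classical image-conditioning chain (ROI extraction, median denoising,
    mean calibration, CLAHE enhancement), Otsu-based vessel candidate
    extraction and mask ingestion, polar-coordinate optic disc boundary
    segmentation with minimum-enclosing-circle papillary diameter
    calibration, topology-preserving centerline skeletonization with
    branch-point graph decomposition, and the morphometric parameter set:
    pointwise vessel diameter (micrometres via the 1.5 mm papillary
    reference), circumradius-curvature tortuosity, box-counting fractal
    dimension, vascular density, branching angle, arteriole-to-venule
    ratio, and zonal (C1-C4 annuli) statistics. A deterministic phantom
    generator provides synthetic fundus images with analytic ground truth
    for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
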