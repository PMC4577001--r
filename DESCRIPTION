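Package: drrreg
Title: Intensity-Based 2D/3D Rigid Registration of CT to Orthogonal Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-position verification by intensity-based 2D/3D rigid
    registration. A planning CT volume is registered to a pair of orthogonal
    2D radiographs by casting digitally reconstructed radiographs (DRRs)
    through the CT with a divergent-beam ray-tracing projector, scoring
    similarity inside calculation regions of interest with normalized mutual
    information, gradient difference and zero-mean normalized
    cross-correlation, and minimizing the combined cost over the six rigid
    degrees of freedom with a multi-resolution Powell-Brent direction-set
    optimizer. Includes the target-registration-error evaluation protocol
    (perturb, re-register, offset-subtract, summarize) and a parametric
    head/pelvis/lung phantom generator producing CT volumes and synthetic
    radiographs so the full pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
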