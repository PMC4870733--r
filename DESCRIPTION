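Package: mrikin
Title: Marker-Less MRI-Based Quantification of Rigid-Body Joint Displacements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a marker-less, MRI-only technique for quantifying rigid-body
    displacements between solid objects, aimed at joint (e.g. inter-vertebral)
    kinematics. Provides a synthetic phantom and slice-imaging simulator (two
    bored cubes, a four-plate bead calibration grid, thick-slab partial-volume
    rendering), slice-volume calibration by planar direct linear transformation
    of digitized bead centroids, automated rotoscoping (model-to-image rigid
    registration of solid models to single-plane or biplanar MR-like slices by
    derivative-free silhouette matching), extraction of joint-coordinate-system
    displacements, and a complete test-retest reliability analysis:
    between-session coefficients of variation, ICC(2,1) with confidence
    intervals, Bland-Altman limits of agreement, heteroscedasticity
    classification and ratio limits of agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
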