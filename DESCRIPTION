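Package: morphoforce
Title: Nano-Newton Tissue Force Inference from Intravital Hydrogel Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to infer tissue-scale mechanical forces from the deformation of
    elastic hydrogel cylinders printed inside living embryos. Provides a geometrically
    nonlinear plane finite-element model of a thin-walled ring compressed between rigid
    surfaces, calibration of the parametric stiffness law k = alpha * H * (t/D)^3 * E by
    least squares over a geometry/stiffness parameter sweep, Hertz fitting of AFM
    indentation curves and uniaxial modulus estimation, time-lapse image analysis
    (drift registration, segmentation, bounding-rectangle width), and the full
    width-to-force pipeline: strain, force, stored elastic energy, impulse, ATP
    equivalents and cohort statistics. Seeded synthetic generators emulate every input
    class so the whole pipeline is testable without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
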