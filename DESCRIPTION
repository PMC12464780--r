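Package: memcurve
Title: Membrane Curvature Thermodynamics from Monolayer Isotherms and
    Lateral Pressure Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for studying how ceramide/sphingomyelin
    ratios control membrane curvature in matrix-vesicle membrane models.
    Computes monolayer isotherm thermodynamics (compressibility modulus,
    excess molecular area, excess Gibbs energy of mixing), elastic
    constants from lateral pressure profiles (spontaneous bending moment
    and Gaussian modulus as first and second z-moments), and
    surface-geometry descriptors of simulated bilayers (curvature order
    parameter, area per lipid, head-to-head thickness) from fitted
    periodic height fields. A synthetic-data generator with closed-form
    ground truth stands in for Langmuir-trough measurements and molecular
    dynamics outputs so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
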