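Package: artiSSM
Title: Articulating Multi-Component Statistical Shape Models of Jointed Anatomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Construction, articulation, evaluation, and interrogation of
    multi-component statistical shape models (SSMs) of jointed anatomical
    structures such as the equine distal limb. Provides vertex-order-preserving
    triangle-mesh input/output (PLY, OBJ, STL, legacy VTK polydata), an
    articulated skeleton with spherical joint angles and flexion transforms,
    stiffness-annealed elastic surface registration for dense correspondence,
    scale and single-axis pose normalization, principal component analysis of
    composite shape vectors with principal geodesic handling of rotation-axis
    directions on the unit sphere, automatic anatomical biometrics and
    biometric-driven model morphing, standard model quality metrics
    (compactness, specificity, generalizability), and a synthetic
    articulated-limb generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
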