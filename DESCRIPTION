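Package: lungmech
Title: 4D Micro-CT Lung Biomechanics: Gating, Segmentation, Registration,
    Strain Mapping and Acinar Conformation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying lung tissue biomechanics from dynamic
    (4D) micro computed tomography of the breathing lung. Implements
    retrospective cardiorespiratory gating of projection streams,
    Otsu-based airspace and vessel segmentation with erosion-profile
    classification into proximal, intermediate and terminal structures,
    pairwise non-rigid B-spline image registration composed into Lagrangian
    displacement fields, skeleton-based detection of recruited airspaces,
    voxel-wise volumetric strain and internal surface-area change through
    moving-least-squares corrected divergence operators, and power-law
    fitting of the surface-volume relation S = k*V^n to classify acinar
    conformational change. A synthetic phantom generator with analytic
    ground truth (displacement fields, labels, volumes and surface areas)
    makes every stage testable without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    RNifti
Config/testthat/edition: 3
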