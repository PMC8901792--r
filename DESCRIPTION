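Package: brainwarp
Type: Package
Title: Spatiotemporal Registration of Developing Brain Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deformable registration and temporal staging for 3D light-sheet
    volumes of the perinatal mouse brain. Implements contour-enhancing
    preprocessing (per-slice histogram equalization, background suppression,
    PCA pre-alignment, Laplacian-of-Gaussian contour extraction), free-form
    deformation on a regular node grid optimized by attention-gated simulated
    annealing with an L1 volume-change deformation-energy penalty,
    mirror-symmetrization and hemisphere splitting, classical
    multidimensional scaling of pairwise image distances to estimate
    per-sample developmental ("adjusted") ages, and Gaussian-weighted average
    and differential volume rendering of developmental dynamics. Includes a
    synthetic phantom generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    RNifti,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
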