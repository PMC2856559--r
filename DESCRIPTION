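Package: tagflow3d
Title: 3D Tagged Cardiac MR Deformation Analysis by Hierarchical Optical Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying left-ventricular deformation from 3D SPAMM-tagged
    cardiovascular MR image sequences. Provides a synthetic tagged left-ventricle
    phantom generator with exactly known ground-truth motion (three tag-plane
    families, T1 tag fading, systolic torsion, radial contraction and longitudinal
    shortening), a hierarchical coarse-to-fine 3D optical-flow tracker (global
    translation/rotation alignment followed by per-voxel Gauss-Newton SSD
    minimization on Laplacian-filtered data, with Lagrangian integration of
    pair-wise flow over systole), Green-Lagrange strain and principal-strain
    analysis, left-ventricular sectorization with regional strain tables and
    bull's-eye maps, and validation experiments (per-axis RMS tracking error,
    tag-angle sweep, noise sensitivity, 2D-vs-3D comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    mgcv,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
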