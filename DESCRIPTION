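Package: bonespm
Title: Spatial Analysis of Bone Density, Microstructure and Micro-Finite-Element
    Biomechanics in HR-pQCT Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical parametric mapping of distal-radius bone from
    HR-pQCT-like calibrated volumes. Generates synthetic tubular bone phantoms
    and two-group cohorts with known ground truth; segments periosteal,
    cortical and trabecular compartments with a soft (fuzzy) cortical
    membership; computes standard compartmental metrics (Tb.BMD, Tb.BV/TV,
    Tb.N, Tb.Sp, Ct.BMD, Ct.Th); runs linear voxel-based micro-finite-element
    analysis under axial compression (stiffness, failure load, strain energy
    density); builds homogenized trabecular voxel maps and Laplace-streamline
    cortical surface maps; spatially normalizes maps to a common template with
    shape principal components; and performs adjusted group comparisons,
    partial Spearman correlation maps, Fisher-Z group comparison of
    correlations and false-discovery-rate correction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    RNifti,
    stats,
    grDevices,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
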