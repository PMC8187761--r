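---
title: "Methods: spatial analysis of bone density, microstructure and micro-FE biomechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial analysis of bone density, microstructure and micro-FE biomechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bonespm)
```

# Overview

`bonespm` implements a statistical parametric mapping (SPM) pipeline for
HR-pQCT-like images of the distal radius: calibrated BMD volumes are
segmented into periosteal, cortical and trabecular compartments; standard
compartmental metrics, a linear voxel-based micro-finite-element (micro-FE)
model, smooth trabecular voxel maps and Laplace-streamline cortical surface
maps are computed per subject; maps are brought into a common template
space; and group statistics (covariate-adjusted comparisons, partial
Spearman correlation maps, Fisher-Z between-group comparison of
correlations, FDR correction) are evaluated globally and at every voxel or
vertex. Because clinical HR-pQCT images of this kind are generally not
redistributable, the package ships a synthetic-cohort generator with known
ground truth; every algorithmic claim in the test suite is checked against
closed forms or brute-force oracles on those phantoms.

# The synthetic phantom and cohort model

A phantom is a tube: a dense cortical shell whose outer radius and
thickness vary smoothly along the axis (the distal radius flares toward the
distal end, so the default radius profile tapers by 12 % over the scan),
filled with a periodic trabecular lattice. Lattice flavours are `plates`
(a single family of plates normal to the bone axis — chosen so the interior
bone fraction is exactly thickness/period, which the tests exploit),
`rods` (axial rods) and the default `plates+rods` (two orthogonal axial
plate families plus offset axial rods), which gives both plate-like and
rod-like topology as in real radii. Tissue is assigned a BMD of
900 mg/cm^3 and marrow 30 mg/cm^3; the volume is blurred with a Gaussian
(standing in for the scanner point-spread function and partial-volume
effect) and corrupted with additive Gaussian noise. The default scan
geometry is first-generation HR-pQCT: 0.082 mm isotropic voxels; a full
scan of 110 slices spans 9.02 mm.

Study-scale defaults are desk-scale: 64^3-voxel grids, outer radius 1.9 mm,
cortical thickness 0.5 mm, lattice period 0.8 mm and thickness 0.1 mm
(BV/TV about 0.2). These are deliberately smaller than a real radius
(roughly 7 mm outer radius on a 168^2 x 110 grid) so that cohort-level
simulations run in minutes; all geometric algorithms are
resolution-independent and are additionally tested for resolution
invariance.

A cohort draws per-subject multipliers for bone volume fraction, cortical
thickness and tissue BMD (log-scale-free normal multipliers with a 12 %
coefficient of variation; global size 5 % CV plus band-limited sinusoidal
radius perturbations, which is what the shape PCA later feeds on). The
fracture group's means are shifted by multiplicative effect sizes whose
defaults are the control-to-fracture ratios reported for distal-radius
Colles'-fracture cohorts (BV/TV 0.19/0.23, cortical thickness 0.95/1.01,
cortical BMD 858.4/886.0). Covariates (age 64.6 +/- 9.3 y, height
161.5 +/- 5.6 cm, weight 74.0 +/- 15.7 kg) are drawn independently of
group, mirroring the non-significant covariate differences in such
cohorts. A per-subject motion grade 1-5 is sampled as metadata only;
grades above 3 are excluded by the pipeline before analysis, with the
exclusion counted in the run manifest.

Each subject also carries per-slice latent fields for BV/TV and tissue
BMD. An axial correlation-gradient parameter `gradient_strength` makes the
two fields share a common factor with weight growing linearly from the
distal end (slice 1) to the proximal end: cohorts built with this gradient
are the ground truth for the "stronger correlations proximally than
distally" checks.

What the generator does *not* emulate: scanner projection physics, beam
hardening, reconstruction artifacts, real motion artifacts, anatomical
asymmetry, or realistic trabecular anisotropy (exposed as the lattice kind
rather than asserted). Passing tests therefore demonstrate correctness of
the measurement and statistics chain on geometrically faithful synthetic
data, not clinical validity on scanner images.

# Segmentation

The periosteal surface is found by box-smoothing (0.1 mm), thresholding
(`>=` is foreground; the default threshold is the Otsu split of the volume
histogram, with the threshold placed at the midpoint of the two class
means so that spiky histograms are handled sensibly), morphological closing
(3-voxel ball), keeping the largest 3D-connected component, and filling
each slice.

The compartment split works on the homogenized density: BMD averaged over
a cube kernel wider than the trabecular spacing (half-width
`2 * min_cortex_voxels`, default 6 voxels) separates the solid shell from
the lattice-like interior, and the Otsu threshold of that map sits at the
midpoint of the two modes — for a flat interface this level set crosses
exactly at the cortex boundary. A literal "bone component connected to the
periosteal boundary" rule does not work here: trabeculae are physically
connected to the shell, so the connected component would be the entire
skeleton. The final cortical compartment is the pore-closed bone inside
the non-trabecular region, so the endosteal boundary is carried by the
bone/marrow interface (sub-voxel accurate for blurred step edges) rather
than by the homogenized level set (which is biased by curvature). A
one-voxel guard band between the compartments absorbs the staircase of the
level set; the spatial analysis erodes the trabecular domain anyway.

Two self-calibration details matter in cohorts. First, the bone threshold
defaults to the Otsu split *inside the trabecular region*, which keeps
partial-volume-thinned trabeculae (sub-voxel plate thickness is the norm at
82 um) in the bone mask; if the trabecular histogram is effectively
unimodal (a hollow shell), it falls back to the marrow/cortex midpoint.
Second, `cohort_metrics()` and the pipeline calibrate thresholds once, on
a reference subject, and hold them fixed across the cohort: per-subject
self-calibration would absorb genuine group differences in density and
structure — exactly as the manufacturer's standard analysis uses fixed
thresholds for all patients.

The soft cortical classification is the standard quadratic s-shaped
membership function; its anchors default to the 10th and 90th percentiles
of intra-cortical BMD so membership 0 means marrow-like and 1 means fully
mineralized tissue. For the endosteal boundary the package also provides a
non-local fuzzy c-means refinement (`nlfcm_endosteal()`): features are the
BMD map, the binary bone mask and the periosteal distance, z-scored; the
spatial term follows the FCM_S family, augmenting each voxel's distance to
a centroid with the distance of the averaged features of its K most
similar patches (patch half-width 1, search half-width 3, K = 6, weight
0.5, fuzzifier 2, tolerance 1e-5, at most 100 iterations). This objective
is non-increasing under the alternating updates — a property the tests
assert per iteration — and reduces to plain FCM at weight 0. Cluster
identity is resolved by mean periosteal distance (cortical = nearer).

# Standard metrics

Trabecular BMD and BV/TV are direct averages over the trabecular mask (the
bone mask, not a density surrogate, defines BV/TV; synthetic volumes have
no calibration drift to compensate). Trabecular number is the reciprocal
of the mean centre-to-centre mid-axis spacing measured by distance
transforms: the volume-weighted mean local thickness (largest inscribed
sphere) of the marrow phase plus that of the bone phase. Spheres truncated
by the axial field of view are excluded from the means; the local
thickness convention is centre-to-centre, so a slab w voxels wide reads
w+1 voxel diameters and the plate-lattice oracle (Tb.N = 1/period within
half a voxel) fixes the overall calibration. Tb.Sp is derived as
`(1 - BV/TV) / Tb.N`. Cortical thickness is the annular mean: cortical
volume divided by the periosteal lateral area, with per-slice perimeters
measured on the 0.5 contour of the lightly smoothed mask (sub-voxel, and
accurate for the staircase boundary). Note the annular thickness is
`t (1 - t/2b)` for a cylinder of outer radius `b` and wall `t`; at desk
scale (`t/b` about 0.28) it is visibly smaller than the radial wall
thickness the streamlines measure — the two agree after that geometric
factor, which one test checks explicitly.

# Micro-finite-element analysis

One 8-node hexahedral element per bone voxel; isotropic linear elasticity
with E = 6829 MPa and nu = 0.3; 1 % axial compression. Elements whose
6-connected component does not reach both axial end faces of the element
set carry no load and are pruned (count reported). Boundary conditions
follow the uniaxial-stress convention: end faces are constrained axially
only, leaving lateral expansion free, which makes the solid-beam stiffness
exactly E*A/L and the SED field uniform at `E eps^2 / 2` (0.34145 for the
defaults — on the MPa scale conventionally labelled J/mm^3 in this field).
A `lateral = "pinned"` option fully fixes the end faces instead. The
sparse symmetric system (assembled with the Matrix package) is solved by
Jacobi-preconditioned conjugate gradients to a relative residual of 1e-6;
with only axial constraints the free-free block has three lateral
rigid-body null modes, but the right-hand side is orthogonal to them, so
CG converges in their quotient space (verified against a dense
pseudo-inverse solve on small random models). Failure load uses the
critical-strain tissue-fraction criterion: the energy-equivalent effective
strain `sqrt(2 SED / E)` is scaled so that 2 % of tissue volume exceeds
0.7 % strain; with a linear model this is a pure rescaling of the reaction
force, and is invariant to the applied strain.

# Parametric maps

Trabecular voxel maps are kernel means over the spherical neighbourhood
(uniform weights; radius 11 voxels for BMD, SED and local BV/TV, 5 voxels
for the inter-trabecular distance), restricted to the trabecular domain
and undefined where the kernel meets no domain voxel. The map domain is
the trabecular mask eroded by the kernel radius, so no kernel touches the
cortex. The inter-trabecular distance (Tb.1/N, reported in voxels) is the
local-thickness transform of the marrow phase, zero on bone. The SED map
places element energy densities on bone voxels with marrow at zero. At
desk scale the pipeline runs these kernels at reduced radii (5/3 voxels,
with erosion 5) purely because the phantom cross-section is itself only
about 23 voxels in radius; the full-scale defaults remain r = 11/5.

Cortical surface maps follow the Laplace-streamline construction. The
potential solves the Laplace equation on the cortical compartment with
Dirichlet bands one-two voxels wide just outside the shell (0 periosteal,
1 endosteal; 6-neighbour finite differences, SOR with relative tolerance
1e-6; axial end faces are natural boundaries). The periosteal mesh
exploits the tubular anatomy: each slice's contour is sampled at equally
spaced rays from the slice centroid, with sub-voxel radii from bisecting
the 0.5 level of the smoothed mask, and consecutive rings are stitched
into triangles — every subject shares the (slice, angle) topology, which
makes cross-subject vertex correspondence and shape PCA straightforward.
Streamlines integrate the normalized potential gradient from each vertex
(explicit Euler, step = half a voxel) and terminate at the sub-voxel 0.5
crossing of the smoothed cortical indicator; terminating on a potential
iso-level instead would inherit the half-voxel offset of the Dirichlet
bands. Arc length is the apparent cortical thickness; the streamline
integral of the soft membership is the porosity-weighted thickness
(SIT <= apparent thickness always, since membership <= 1); BMD and SED are
arc-length-weighted means along the trajectory (composite trapezoid on the
integration points).

# Spatial normalization and shape covariates

Registration is driven purely by periosteal geometry: the squared
difference of signed distance maps (synthetic and clinical intensity
distributions differ; the surface is the correspondence that matters). A
similarity stage (translation, rotation, single log-scale) then a full
affine stage (anisotropic log-scales and shears) are optimized by
Nelder-Mead over about 10^4 surface-band sample points, rotations taken
about the band centroid. A stage that worsens the metric is an error. The
deformable stage is a demons-type iteration on the clamped (±8 voxels) and
lightly smoothed distance maps — the discrete EDT is bumpy at the voxel
scale and the raw residual would drive the field into that noise; updates
are capped at one voxel per iteration and the accumulated field is
smoothed with a 2-voxel Gaussian. The stage is accepted only if the
surface-band mean absolute error improves; on small warps the affine stage
already sits at the EDT noise floor (about a third of a voxel) and the
deformable stage is a no-op, which is the intended behaviour. The
transform maps template coordinates to subject coordinates, so resampling
parametric maps onto the template grid (trilinear, `NA` propagating) uses
it directly. Surface values transfer by mapping each template vertex
through the transform and interpolating barycentrically on the nearest
subject face, with the point-to-face distance logged as QC.

The template defaults to the subject with the median periosteal volume; an
optional fixed-iteration refinement registers all subjects, averages the
warped signed distance maps, and re-extracts the zero level. Shape
covariates are the first principal components of generalized-Procrustes-
aligned vertex coordinates; translation and rotation are removed but scale
is retained, since bone size is biology rather than nuisance here. The
default keeps `min(k at 90 % variance, 4)` components, mirroring the
convention of using the first four PCs for shape adjustment.

# Statistics

Global group comparisons are ordinary least squares of each metric on a
group indicator plus age, height and weight, with the group coefficient's
two-sided t-test. Interrelationships use partial Spearman correlations:
mid-rank transform, least-squares residualization on the covariates,
Pearson correlation of the residuals, and a t reference with
`n - 2 - k` degrees of freedom. Mid-ranks matter because lattice-derived
maps tie often. Between-group comparison of correlations uses the Fisher Z
transformation with effective sizes `n - 3 - k` (the covariate-corrected
form; `df_correction = FALSE` restores the classic `n - 3`). Two caveats
are documented rather than silently absorbed: the Fisher variance is exact
for Pearson correlations of bivariate normals, and is known to be
somewhat anticonservative when applied to Spearman correlations at
moderate population correlation (variance closer to `(1 + rho^2/2)/(n-3)`);
the package implements the classic transformation that the published
method prescribes and calibrates it on Pearson nulls.

Voxel- and vertex-wise maps apply the same partial Spearman at every
template location within each group (complete-data locations share one
covariate projector, so the map computation is a few matrix products), and
Benjamini-Hochberg FDR at q = 0.05 is applied per map over the locations
that pass the minimum-n rule (default: at least 90 % of the group defined
at the location; the rule is a package choice, the analysis is insensitive
to it away from domain edges). Difference maps compare the group
correlation maps location-wise with Fisher Z (difference reported as
fracture minus control) and FDR-correct the resulting p map. Global
correlation tables use subject-level means of the parametric maps before
spatial normalization, exactly as the published analysis does.

# Numerical choices and limitations

* Thresholding ties: `>=` is foreground everywhere.
* Otsu thresholds return the midpoint of the class means at the optimal
  split, well-defined on spiky histograms.
* The EDT is exact (Felzenszwalb lower-envelope, separable); local
  thickness paints inscribed spheres from the distance ridge, so its
  complexity is governed by the medial surface, and its convention is
  centre-to-centre (a w-voxel slab reads w+1).
* The FE solver budget is `max(500, 10 sqrt(n_nodes))` CG iterations at
  tolerance 1e-6; non-convergence is an error carrying the residual.
* SOR for the Laplace problem uses omega = 1.9 and a relative-change
  tolerance of 1e-6; non-convergence returns the last iterate flagged.
* Streamlines that leave the field before mid-potential, or exceed the
  length cap, are undefined-flagged and propagate `NA` into the surface
  maps.
* Degenerate inputs are flagged, not crashed: hollow shells give
  BV/TV = 0 with Tb.Sp undefined; identical NL-FCM features set the
  degenerate flag; constant variables give undefined correlations.
* Problem sizes in the tests (48-64 voxel grids, cohorts of 8-50, 20
  replicate studies, 2000-simulation calibrations) were chosen as the
  smallest sizes at which the closed-form and oracle tolerances are
  meaningful; they are the package's documented study conditions.
* Known limitations: no scanner physics or motion simulation; axial-only
  FE loading (no fall configuration); no direct porosity quantification
  (porosity enters only through the soft membership, as intended); the
  deformable registration is a surface-geometry method and will not
  recover internal-only deformation. The generator's phantoms are
  circularly symmetric in-plane, so in-plane rotation is a flat direction
  of the registration metric on them — harmless for distance-map and
  map-resampling accuracy, but transform *parameters* are only
  identifiable on asymmetric shapes (real radii are asymmetric; the
  transform-recovery tests use an elliptical tube).
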