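#' @useDynLib bonespm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif prcomp sd cor pt pnorm p.adjust quantile
#'   lm lm.fit coef optim median complete.cases relevel qr qr.resid qr.R
#'   chol2inv
#' @importFrom ggplot2 autoplot
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

# evaluate code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic distal-radius phantom
#'
#' Describes a tubular bone phantom: a dense cortical shell whose outer radius
#' and thickness vary smoothly along the axis, an interior trabecular lattice
#' (plates, rods, or both), BMD levels for bone and marrow, and the imaging
#' degradations (Gaussian blur standing in for the scanner point-spread
#' function / partial-volume effect, then additive Gaussian noise).
#'
#' Default scan geometry follows first-generation HR-pQCT: 0.082 mm isotropic
#' voxels; a full-length scan of 110 slices spans 9.02 mm axially.
#'
#' @param grid_shape integer length-3, voxels per axis (axis 3 = bone axis,
#'   slice 1 = distal).
#' @param spacing voxel spacing in mm (isotropic default 0.082).
#' @param outer_radius_mm periosteal outer radius in mm: a scalar, or a
#'   profile with one value per slice.
#' @param cortical_thickness_mm cortical shell thickness in mm (scalar or
#'   per-slice profile).
#' @param taper relative linear widening of the outer radius from proximal to
#'   distal end (the distal radius flares distally).
#' @param trabecular_period_mm lattice period in mm.
#' @param trabecular_thickness_mm trabecular plate/rod thickness in mm.
#' @param lattice_kind `"plates"` (one parallel plate family, interior bone
#'   fraction = thickness/period exactly), `"rods"` (axial rods), or
#'   `"plates+rods"` (two orthogonal plate families plus offset axial rods).
#' @param bmd_bone,bmd_marrow BMD levels (mg/cm^3) of mineralized tissue and
#'   marrow background.
#' @param noise_sd additive Gaussian noise sd (mg/cm^3), applied after blur.
#' @param blur_sigma Gaussian blur sd in mm (0 = none).
#' @param lattice_phase length-2 phase offsets (fraction of a period) of the
#'   lattice in x and y; jittered per subject in cohorts.
#' @param seed integer RNG seed for the noise realization.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         spacing = 0.082,
                         outer_radius_mm = 1.9,
                         cortical_thickness_mm = 0.5,
                         taper = 0.12,
                         trabecular_period_mm = 0.8,
                         trabecular_thickness_mm = 0.1,
                         lattice_kind = c("plates+rods", "plates", "rods"),
                         bmd_bone = 900,
                         bmd_marrow = 30,
                         noise_sd = 20,
                         blur_sigma = 0.082,
                         lattice_phase = c(0, 0),
                         seed = 1L) {
  lattice_kind <- match.arg(lattice_kind)
  grid_shape <- as.integer(grid_shape)
  nz <- grid_shape[3]
  expand_profile <- function(p, what) {
    if (length(p) == 1) p <- rep(p, nz)
    if (length(p) != nz)
      stop(sprintf("%s must be scalar or one value per slice", what))
    p
  }
  # distal (slice 1) is wider than proximal for taper > 0
  rad <- expand_profile(outer_radius_mm, "outer_radius_mm")
  if (length(outer_radius_mm) == 1 && taper != 0) {
    zfrac <- (seq_len(nz) - 1) / max(1, nz - 1)
    rad <- rad * (1 + taper * (0.5 - zfrac))
  }
  ct <- expand_profile(cortical_thickness_mm, "cortical_thickness_mm")
  spec <- list(grid_shape = grid_shape, spacing = spacing,
               outer_radius_profile = rad, cortical_thickness_profile = ct,
               trabecular_period = trabecular_period_mm,
               trabecular_thickness = trabecular_thickness_mm,
               lattice_kind = lattice_kind,
               bmd_bone = bmd_bone, bmd_marrow = bmd_marrow,
               noise_sd = noise_sd, blur_sigma = blur_sigma,
               lattice_phase = lattice_phase, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (any(outer_radius_profile <= cortical_thickness_profile))
      stop("outer radius must exceed cortical thickness on every slice")
    if (trabecular_thickness >= trabecular_period)
      stop("trabecular thickness must be smaller than the lattice period")
    if (bmd_bone <= bmd_marrow)
      stop("bone BMD must exceed marrow BMD")
    if (noise_sd < 0 || blur_sigma < 0)
      stop("noise_sd and blur_sigma must be non-negative")
    half_extent <- (grid_shape[seq_len(2)] - 1) * spacing / 2
    if (max(outer_radius_profile) > min(half_extent) - spacing)
      stop("grid too small: outer radius does not fit inside the grid ",
           "with a one-voxel margin")
  })
  invisible(spec)
}

# Interior lattice indicator for one slice at axial position zmm; xmm/ymm are
# voxel-centre coordinates (origin at the grid corner), phases in fractions
# of a period. "plates" is a single family of parallel plates normal to the
# bone axis (interior bone fraction = thickness/period by construction);
# "rods" are axial rods; "plates+rods" unions two orthogonal axial plate
# families with offset axial rods.
lattice_indicator <- function(spec, xmm, ymm, zmm) {
  p <- spec$trabecular_period
  t <- spec$trabecular_thickness
  ph <- spec$lattice_phase * p
  nx <- length(xmm); ny <- length(ymm)
  eps <- 1e-7 * p # guard against %% rounding at period boundaries
  inplate <- function(v) { m <- v %% p; m < t - eps | m > p - eps }
  fx <- inplate(outer(xmm + ph[1], rep(1, ny)))
  fy <- inplate(outer(rep(1, nx), ymm + ph[2]))
  switch(spec$lattice_kind,
         "plates" = matrix(inplate(zmm + ph[1]), nx, ny),
         "rods" = fx & fy,
         "plates+rods" = fx | fy |
           (inplate(outer(xmm + ph[1] + p / 2, rep(1, ny))) &
            inplate(outer(rep(1, nx), ymm + ph[2] + p / 2))))
}

#' Generate a phantom volume from its specification
#'
#' Builds the noiseless labelled geometry (cortical annulus per slice plus the
#' interior lattice), assigns BMD levels, Gaussian-blurs by `blur_sigma` and
#' adds zero-mean Gaussian noise. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param per_slice_bvtv_scale optional per-slice multiplier on trabecular
#'   thickness (axial modulation of bone volume fraction).
#' @param per_slice_bmd optional per-slice tissue BMD values overriding
#'   `bmd_bone`.
#' @return a [bone_volume()] with attribute `ground_truth` (list with the
#'   noiseless bone mask and the geometric profiles).
#' @export
make_phantom <- function(spec, per_slice_bvtv_scale = NULL,
                         per_slice_bmd = NULL) {
  validate_phantom_spec(spec)
  d <- spec$grid_shape
  sp <- rep(spec$spacing, 3)
  cx <- (d[1] - 1) / 2 * sp[1]
  cy <- (d[2] - 1) / 2 * sp[2]
  xmm <- (seq_len(d[1]) - 1) * sp[1] - cx
  ymm <- (seq_len(d[2]) - 1) * sp[2] - cy
  r2 <- outer(xmm^2, ymm^2, "+")
  vol <- array(0, d)
  bone <- array(FALSE, d)
  base_t <- spec$trabecular_thickness
  for (z in seq_len(d[3])) {
    R <- spec$outer_radius_profile[z]
    Ri <- R - spec$cortical_thickness_profile[z]
    inside <- r2 <= R^2
    interior <- r2 <= Ri^2
    sl <- spec
    if (!is.null(per_slice_bvtv_scale))
      sl$trabecular_thickness <- min(base_t * per_slice_bvtv_scale[z],
                                     0.95 * spec$trabecular_period)
    lat <- lattice_indicator(sl, xmm + cx, ymm + cy, (z - 1) * sp[3])
    bone_sl <- (inside & !interior) | (interior & lat)
    bmd_z <- if (is.null(per_slice_bmd)) spec$bmd_bone else per_slice_bmd[z]
    sl_vals <- matrix(0, d[1], d[2])
    sl_vals[inside] <- spec$bmd_marrow
    sl_vals[bone_sl] <- bmd_z
    vol[, , z] <- sl_vals
    bone[, , z] <- bone_sl
  }
  if (spec$blur_sigma > 0)
    vol <- fft_convolve3(vol, gaussian_kernel3(spec$blur_sigma, sp))
  if (spec$noise_sd > 0)
    vol <- vol + with_seed(spec$seed,
                           array(rnorm(prod(d), 0, spec$noise_sd), d))
  out <- bone_volume(vol, sp)
  attr(out, "ground_truth") <- list(
    bone_mask = bone,
    outer_radius_profile = spec$outer_radius_profile,
    cortical_thickness_profile = spec$cortical_thickness_profile,
    interior_bone_fraction = {
      interior_all <- sweep(array(r2, d), 3,
                            (spec$outer_radius_profile -
                             spec$cortical_thickness_profile)^2, "<=")
      sum(bone & interior_all) / max(1, sum(interior_all))
    })
  out
}

#' Specification of a synthetic two-group cohort
#'
#' Defines the statistical structure of a control vs. fracture cohort:
#' per-group sample sizes, multiplicative fracture-group effect sizes on bone
#' volume fraction, cortical thickness and tissue BMD, covariate distributions
#' (drawn independently of group), inter-subject size/shape variation, and an
#' axial correlation-gradient parameter that makes the per-slice latent fields
#' of BV/TV and BMD share a common factor more strongly proximally than
#' distally.
#'
#' Default effect sizes are the control-to-fracture mean ratios observed for
#' Tb.BV/TV (0.19/0.23), Ct.Th (0.95/1.01) and Ct.BMD (858.4/886.0) in
#' published distal-radius Colles'-fracture cohorts; default covariate
#' distributions are age 64.6 +/- 9.3 y, height 161.5 +/- 5.6 cm, weight
#' 74.0 +/- 15.7 kg.
#'
#' @param n_control,n_fracture per-group subject counts (each >= 4).
#' @param bv_tv_effect,ct_th_effect,bmd_effect multiplicative fracture-group
#'   effects (> 0; 1 = no effect).
#' @param age_mean,age_sd,height_mean,height_sd,weight_mean,weight_sd
#'   covariate distributions (normal).
#' @param subject_cv coefficient of variation of per-subject multipliers on
#'   bone volume fraction / cortical thickness / tissue BMD.
#' @param size_cv coefficient of variation of the per-subject global size
#'   scale; `shape_pert` sets the amplitude (fraction of radius) of the
#'   band-limited sinusoidal perturbation of the radius profile.
#' @param gradient_strength in `[0, 1]`: at the proximal end the BV/TV and
#'   BMD latent fields share a factor with this weight, at the distal end
#'   they are independent.
#' @param field_sd relative sd of the per-slice latent variation.
#' @param motion_grade_probs probabilities of motion grades 1..5.
#' @param base_spec a [phantom_spec()] used as the template geometry.
#' @param seed integer RNG seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_control = 98, n_fracture = 84,
                        bv_tv_effect = 0.19 / 0.23,
                        ct_th_effect = 0.95 / 1.01,
                        bmd_effect = 858.4 / 886.0,
                        age_mean = 64.6, age_sd = 9.3,
                        height_mean = 161.5, height_sd = 5.6,
                        weight_mean = 74.0, weight_sd = 15.7,
                        subject_cv = 0.12, size_cv = 0.05,
                        shape_pert = 0.03,
                        gradient_strength = 0,
                        field_sd = 0.1,
                        motion_grade_probs = c(0.55, 0.3, 0.1, 0.04, 0.01),
                        base_spec = phantom_spec(),
                        seed = 1L) {
  spec <- list(n_control = as.integer(n_control),
               n_fracture = as.integer(n_fracture),
               bv_tv_effect = bv_tv_effect, ct_th_effect = ct_th_effect,
               bmd_effect = bmd_effect,
               age_mean = age_mean, age_sd = age_sd,
               height_mean = height_mean, height_sd = height_sd,
               weight_mean = weight_mean, weight_sd = weight_sd,
               subject_cv = subject_cv, size_cv = size_cv,
               shape_pert = shape_pert,
               gradient_strength = gradient_strength, field_sd = field_sd,
               motion_grade_probs = motion_grade_probs,
               base_spec = base_spec, seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_control < 4 || n_fracture < 4)
      stop("each group needs at least 4 subjects")
    if (any(c(bv_tv_effect, ct_th_effect, bmd_effect) <= 0))
      stop("effect sizes must be positive")
    if (any(c(age_sd, height_sd, weight_sd, subject_cv, size_cv,
              field_sd) < 0))
      stop("dispersion parameters must be non-negative")
    if (gradient_strength < 0 || gradient_strength > 1)
      stop("gradient_strength must lie in [0, 1]")
    if (abs(sum(motion_grade_probs) - 1) > 1e-8 || any(motion_grade_probs < 0))
      stop("motion_grade_probs must be a probability vector over grades 1..5")
  })
  invisible(spec)
}

# band-limited smooth perturbation profile over nz slices
smooth_profile_noise <- function(nz, n_modes = 3) {
  z <- (seq_len(nz) - 1) / max(1, nz - 1)
  out <- numeric(nz)
  for (m in seq_len(n_modes))
    out <- out + rnorm(1) / m * sin(pi * m * z + runif(1, 0, 2 * pi))
  out / sqrt(sum(1 / (seq_len(n_modes))^2) / 2)
}

#' Generate a two-group cohort of phantoms with known ground truth
#'
#' Per-subject phantom parameters are drawn from group distributions; the
#' fracture group means are shifted by the multiplicative effect sizes;
#' covariates are drawn independently of group. Per-slice latent fields of
#' BV/TV and tissue BMD carry the axial correlation gradient. Deterministic
#' given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param generate_volumes if `FALSE`, only ground-truth parameters and
#'   latent profiles are produced (fast, for statistical studies).
#' @return a tibble with one row per subject: `id`, `group`, covariates,
#'   `motion_grade`, ground-truth columns (`gt_bvtv`, `gt_ct_th`,
#'   `gt_bmd_bone`, `gt_size`), list-columns `gt_bvtv_profile` /
#'   `gt_bmd_profile` (per-slice latent fields) and `volume`
#'   (each a [bone_volume()]) when requested.
#' @export
make_cohort <- function(spec, generate_volumes = TRUE) {
  validate_cohort_spec(spec)
  n <- spec$n_control + spec$n_fracture
  base <- spec$base_spec
  nz <- base$grid_shape[3]
  with_seed(spec$seed, {
    group <- rep(c("control", "fracture"),
                 c(spec$n_control, spec$n_fracture))
    eff_bv <- ifelse(group == "fracture", spec$bv_tv_effect, 1)
    eff_ct <- ifelse(group == "fracture", spec$ct_th_effect, 1)
    eff_bmd <- ifelse(group == "fracture", spec$bmd_effect, 1)
    draw_pos <- function(mult) pmax(0.2, rnorm(n, 1, spec$subject_cv)) * mult
    m_bv <- draw_pos(eff_bv)
    m_ct <- draw_pos(eff_ct)
    m_bmd <- pmax(0.5, rnorm(n, 1, spec$subject_cv / 2)) * eff_bmd
    size <- pmax(0.7, rnorm(n, 1, spec$size_cv))
    age <- rnorm(n, spec$age_mean, spec$age_sd)
    height <- rnorm(n, spec$height_mean, spec$height_sd)
    weight <- rnorm(n, spec$weight_mean, spec$weight_sd)
    motion_grade <- sample(1:5, n, replace = TRUE,
                           prob = spec$motion_grade_probs)
    zfrac <- (seq_len(nz) - 1) / max(1, nz - 1)
    wz <- spec$gradient_strength * zfrac # proximal = high z
    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      e1 <- smooth_profile_noise(nz)
      e2 <- smooth_profile_noise(nz)
      bv_field <- m_bv[i] * (1 + spec$field_sd * e1)
      bmd_field <- m_bmd[i] *
        (1 + spec$field_sd * (wz * e1 + sqrt(pmax(0, 1 - wz^2)) * e2))
      pert <- smooth_profile_noise(nz)
      sub_spec <- base
      sub_spec$outer_radius_profile <-
        base$outer_radius_profile * size[i] * (1 + spec$shape_pert * pert)
      sub_spec$cortical_thickness_profile <-
        pmin(base$cortical_thickness_profile * m_ct[i],
             0.8 * sub_spec$outer_radius_profile)
      sub_spec$lattice_phase <- runif(2)
      sub_spec$seed <- (spec$seed * 1000L + i) %% .Machine$integer.max
      vol <- NULL
      gt_bvtv <- NA_real_
      if (generate_volumes) {
        vol <- make_phantom(sub_spec,
                            per_slice_bvtv_scale = bv_field,
                            per_slice_bmd = base$bmd_bone * bmd_field)
        gt_bvtv <- attr(vol, "ground_truth")$interior_bone_fraction
      }
      subjects[[i]] <- list(
        spec = sub_spec, volume = vol,
        gt_bvtv = gt_bvtv,
        gt_bvtv_nominal = base$trabecular_thickness * m_bv[i] /
          base$trabecular_period,
        gt_ct_th = mean(sub_spec$cortical_thickness_profile),
        gt_bmd_bone = base$bmd_bone * m_bmd[i],
        gt_size = size[i],
        gt_bvtv_profile = bv_field, gt_bmd_profile = bmd_field)
    }
    tibble(
      id = sprintf("S%03d", seq_len(n)),
      group = group,
      age = age, height = height, weight = weight,
      motion_grade = motion_grade,
      gt_bvtv = vapply(subjects, `[[`, numeric(1), "gt_bvtv"),
      gt_bvtv_nominal = vapply(subjects, `[[`, numeric(1), "gt_bvtv_nominal"),
      gt_ct_th = vapply(subjects, `[[`, numeric(1), "gt_ct_th"),
      gt_bmd_bone = vapply(subjects, `[[`, numeric(1), "gt_bmd_bone"),
      gt_size = vapply(subjects, `[[`, numeric(1), "gt_size"),
      gt_bvtv_profile = lapply(subjects, `[[`, "gt_bvtv_profile"),
      gt_bmd_profile = lapply(subjects, `[[`, "gt_bmd_profile"),
      phantom = lapply(subjects, `[[`, "spec"),
      volume = lapply(subjects, `[[`, "volume"))
  })
}

#' Write a cohort to disk (NIfTI volumes + CSV manifest + JSON spec)
#'
#' @param cohort a tibble from [make_cohort()] with volumes.
#' @param dir output directory (created if needed).
#' @param spec the [cohort_spec()] used (serialized alongside).
#' @return the manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    paths[i] <- file.path(dir, paste0(cohort$id[i], ".nii.gz"))
    write_volume(cohort$volume[[i]], paths[i])
  }
  manifest <- dplyr::select(cohort, -dplyr::any_of(c(
    "volume", "phantom", "gt_bvtv_profile", "gt_bmd_profile")))
  manifest$path <- basename(paths)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (!is.null(spec)) {
    ser <- spec
    ser$base_spec <- unclass(ser$base_spec)
    jsonlite::write_json(unclass(ser), file.path(dir, "cohort_spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(as_tibble(manifest))
}
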