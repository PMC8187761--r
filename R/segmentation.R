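#' Find the periosteal surface of a calibrated volume
#'
#' Edge-finding by smoothing, thresholding (`>=` is foreground), morphological
#' closing, keeping the largest 3D-connected component and filling each slice:
#' the result is one simply connected region per slice containing all bone and
#' marrow inside the periosteal boundary.
#'
#' @param vol a [bone_volume()].
#' @param threshold BMD threshold in mg/cm^3 separating soft tissue from bone;
#'   `NULL` uses the Otsu threshold of the volume histogram.
#' @param closing_radius radius (voxels) of the morphological closing.
#' @param smooth_sigma pre-threshold smoothing scale in mm (box mean).
#' @return logical array (periosteal mask) with the spacing attached.
#' @export
find_periosteal_surface <- function(vol, threshold = NULL, closing_radius = 3,
                                    smooth_sigma = 0.1) {
  sp <- vol_spacing(vol)
  sm <- vol
  if (smooth_sigma > 0) {
    r <- max(1L, round(smooth_sigma / min(sp)))
    sm <- bone_volume(box3_sum(vol_array(vol), r) / (2 * r + 1)^3, sp)
  }
  if (is.null(threshold)) threshold <- otsu_threshold(as.numeric(vol))
  fg <- array(vol_array(sm) >= threshold, dim(vol))
  if (!any(fg)) stop("empty segmentation: no voxel reaches the threshold ",
                     sprintf("%.1f mg/cm^3", threshold))
  fg <- close_mask(fg, closing_radius)
  fg <- largest_component(fg)
  fg <- cpp_fill_slices(as.logical(fg), dim(vol))
  out <- array(fg, dim(vol))
  attr(out, "spacing") <- sp
  attr(out, "threshold") <- threshold
  out
}

#' Split the periosteal interior into cortical and trabecular compartments
#'
#' Threshold-based compartment split. The endosteal boundary is located on
#' the homogenized density: BMD averaged over a spherical kernel wider than
#' the trabecular spacing separates the solid shell (near tissue density;
#' intra-cortical pores smaller than `min_cortex_voxels` do not pull it
#' down) from the lattice-like interior, and the two are split at the Otsu
#' threshold of the homogenized map. For a flat interface between solid
#' cortex and a lattice the homogenized density crosses the inter-mode
#' midpoint exactly at the interface, so the boundary is localized there by
#' construction. The cortical compartment is the above-threshold region
#' connected to the periosteal boundary; the trabecular compartment is the
#' remaining periosteal interior. Bone voxels are then those at or above
#' `bone_threshold`, which defaults to the Otsu threshold *inside the
#' trabecular region* so that partial-volume-thinned trabeculae are still
#' captured.
#'
#' @param vol a [bone_volume()].
#' @param periosteal_mask from [find_periosteal_surface()].
#' @param bone_threshold mg/cm^3; `NULL` uses Otsu inside the trabecular
#'   region.
#' @param min_cortex_voxels pores up to this many voxels across are kept
#'   cortical; the homogenization kernel radius is `2 * min_cortex_voxels`.
#' @param solid_threshold homogenized-BMD level separating shell from
#'   lattice; `NULL` uses the Otsu split of the homogenized map. Cohort
#'   analyses should calibrate it once and hold it fixed, like the other
#'   thresholds.
#' @return list with logical arrays `bone_mask`, `cortical_mask` (shell
#'   region), `trabecular_mask`, the `bone_threshold` used, and
#'   `shell_contiguous` (`FALSE`, with a warning, when the shell region
#'   misses slices).
#' @export
split_compartments <- function(vol, periosteal_mask, bone_threshold = NULL,
                               min_cortex_voxels = 3,
                               solid_threshold = NULL) {
  d <- dim(vol)
  frac <- box_mean(vol_array(vol), periosteal_mask, 2 * min_cortex_voxels)
  fvals <- frac[periosteal_mask]
  fthr <- if (is.null(solid_threshold))
    otsu_threshold(fvals[is.finite(fvals)]) else solid_threshold
  solid <- array(!is.na(frac) & frac >= fthr, d) & periosteal_mask
  # keep only the solid region connected to the periosteal boundary
  boundary_band <- periosteal_mask & !box_erode(periosteal_mask, 1)
  lab <- cpp_label3d(as.logical(solid), d, 26)
  touching <- unique(lab[boundary_band & solid])
  touching <- touching[touching > 0]
  solid <- array(lab %in% touching, d) & solid
  # one-voxel guard band absorbs the staircase of the homogenized level set
  trab <- periosteal_mask & !box_dilate(solid, 1)
  if (is.null(bone_threshold)) {
    # Otsu inside the trabecular region captures partial-volume-thinned
    # trabeculae; when that region is effectively pure marrow (no second
    # mode) fall back to the marrow/cortex midpoint
    tv <- as.numeric(vol)[trab]
    cv <- as.numeric(vol)[solid]
    bone_threshold <- if (length(tv) > 100) otsu_threshold(tv) else Inf
    lo <- if (length(tv)) stats::quantile(tv, 0.05, names = FALSE) else 0
    hi <- if (length(cv)) median(cv) else max(as.numeric(vol))
    if (!is.finite(bone_threshold) ||
        bone_threshold - lo < 0.15 * max(hi - lo, 1))
      bone_threshold <- (lo + hi) / 2
  }
  bone <- array(vol_array(vol) >= bone_threshold & periosteal_mask, d)
  # cortical compartment: bone (with pores below the scale of
  # min_cortex_voxels closed) outside the trabecular region -- the
  # bone/marrow interface, not the homogenized level set, carries the
  # endosteal boundary
  cortical <- box_close(bone, max(1L, min_cortex_voxels %/% 2)) & !trab &
    periosteal_mask
  shell_ok <- all(apply(cortical, 3, any))
  if (!shell_ok)
    warning("cortical shell discontinuous")
  list(bone_mask = bone, cortical_mask = cortical,
       trabecular_mask = trab,
       bone_threshold = bone_threshold,
       solid_threshold = fthr,
       shell_contiguous = shell_ok)
}

#' Fuzzy s-shaped membership function
#'
#' Maps BMD to a degree of cortical-bone membership in `[0, 1]`: 0 at or
#' below `a`, 1 at or above `b`, with the standard quadratic s-curve in
#' between (value 0.5 at the midpoint).
#'
#' @param x BMD values (mg/cm^3).
#' @param a zero-membership BMD; `b` full-membership BMD (`a < b`).
#' @param b see `a`.
#' @return values in `[0, 1]`, same shape as `x`.
#' @export
s_membership <- function(x, a, b) {
  if (a >= b) stop("s-membership requires a < b")
  m <- (a + b) / 2
  u <- (x - a) / (b - a)
  out <- ifelse(x <= a, 0,
         ifelse(x <= m, 2 * u^2,
         ifelse(x < b, 1 - 2 * (u - 1)^2, 1)))
  if (is.array(x)) array(out, dim(x)) else out
}

#' Full compartment segmentation of a calibrated volume
#'
#' Runs periosteal detection, the threshold compartment split, and the soft
#' cortical classification: the s-membership parameters default to the 10th
#' and 90th percentiles of BMD inside the initial cortical mask, and the
#' membership map is zero outside the periosteal mask and restricted to the
#' cortical shell region.
#'
#' @param vol a [bone_volume()].
#' @param threshold,closing_radius passed to [find_periosteal_surface()].
#' @param bone_threshold,min_cortex_voxels,solid_threshold passed to
#'   [split_compartments()].
#' @param membership_percentiles percentiles of intra-cortical BMD defining
#'   the s-function anchors `a` and `b`.
#' @param refine_endosteal if `TRUE`, refine the cortical/trabecular boundary
#'   with [nlfcm_endosteal()] (non-local fuzzy c-means).
#' @param nlfcm_args list of arguments forwarded to [nlfcm_endosteal()].
#' @return a `compartment_segmentation` list: `periosteal_mask`,
#'   `cortical_mask`, `trabecular_mask`, `bone_mask`, `membership`,
#'   `periosteal_distance` (mm), thresholds, and QC flags.
#' @export
segment_volume <- function(vol, threshold = NULL, closing_radius = 3,
                           bone_threshold = NULL, min_cortex_voxels = 3,
                           solid_threshold = NULL,
                           membership_percentiles = c(0.1, 0.9),
                           refine_endosteal = FALSE, nlfcm_args = list()) {
  sp <- vol_spacing(vol)
  peri <- find_periosteal_surface(vol, threshold, closing_radius)
  parts <- split_compartments(vol, peri, bone_threshold, min_cortex_voxels,
                              solid_threshold)
  pdist <- periosteal_distance_map(peri, sp)
  if (refine_endosteal) {
    ref <- do.call(nlfcm_endosteal,
                   c(list(vol = vol, bone_mask = parts$bone_mask,
                          periosteal_mask = peri,
                          periosteal_distance = pdist), nlfcm_args))
    parts$cortical_mask <- ref$cortical_mask
    parts$trabecular_mask <- peri & !ref$cortical_mask
    nlfcm_converged <- ref$converged
  } else nlfcm_converged <- NA
  ct_bmd <- as.numeric(vol)[parts$cortical_mask]
  if (!length(ct_bmd)) ct_bmd <- as.numeric(vol)[parts$bone_mask]
  ab <- stats::quantile(ct_bmd, membership_percentiles, names = FALSE)
  if (!all(is.finite(ab)) || ab[1] >= ab[2])
    ab <- mean(ct_bmd) - c(2, 1) # uniform cortex: tissue-level BMD maps to 1
  memb <- s_membership(vol_array(vol), ab[1], ab[2])
  memb[!peri] <- 0
  structure(list(
    periosteal_mask = peri,
    cortical_mask = parts$cortical_mask,
    trabecular_mask = parts$trabecular_mask,
    bone_mask = parts$bone_mask,
    membership = memb,
    periosteal_distance = pdist,
    spacing = sp,
    periosteal_threshold = attr(peri, "threshold"),
    bone_threshold = parts$bone_threshold,
    solid_threshold = parts$solid_threshold,
    membership_a = ab[1], membership_b = ab[2],
    shell_contiguous = parts$shell_contiguous,
    nlfcm_converged = nlfcm_converged),
    class = "compartment_segmentation")
}

#' @export
print.compartment_segmentation <- function(x, ...) {
  cat("<compartment_segmentation>\n")
  cat(sprintf("  periosteal: %d voxels; cortical: %d; trabecular: %d\n",
              sum(x$periosteal_mask), sum(x$cortical_mask),
              sum(x$trabecular_mask)))
  cat(sprintf("  thresholds: periosteal %.1f, bone %.1f mg/cm^3; s-curve [%.1f, %.1f]\n",
              x$periosteal_threshold, x$bone_threshold,
              x$membership_a, x$membership_b))
  invisible(x)
}
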