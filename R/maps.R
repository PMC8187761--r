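#' Homogenize a voxel map with a spherical kernel
#'
#' Replaces each voxel value by the mean of the input over the spherical
#' kernel of radius `radius` (voxels) intersected with `domain_mask`.
#' Voxels whose kernel meets no domain voxel are `NA` (undefined-flagged).
#'
#' @param map 3D numeric array (or [bone_volume()]).
#' @param domain_mask logical array; the averaging domain.
#' @param radius kernel radius in voxels (>= 1).
#' @return numeric array of the same shape; `NA` outside the defined region.
#' @export
homogenize <- function(map, domain_mask, radius) {
  stopifnot(radius >= 1)
  if (!any(domain_mask)) stop("empty homogenization domain")
  m <- if (inherits(map, "bone_volume")) vol_array(map) else map
  m[is.na(m)] <- 0
  sphere_mean(m, domain_mask & !is.na(map), radius)
}

#' Local bone volume fraction map
#'
#' The bone indicator averaged over the spherical kernel within the
#' trabecular domain: a smooth field in `[0, 1]` suitable for voxel-wise
#' population statistics.
#'
#' @param bone_mask,trabecular_mask logical arrays.
#' @param radius kernel radius in voxels (default 11).
#' @return numeric array in `[0, 1]`, `NA` outside the defined region.
#' @export
local_bvtv <- function(bone_mask, trabecular_mask, radius = 11) {
  out <- homogenize(array(as.numeric(bone_mask), dim(bone_mask)),
                    trabecular_mask, radius)
  pmin(pmax(out, 0), 1)
}

#' Inter-trabecular distance map (Tb.1/N)
#'
#' The local marrow width in voxels: at each marrow voxel, the diameter of
#' the largest sphere fully contained in marrow that covers the voxel
#' (local-thickness transform of the marrow phase); bone voxels take 0.
#'
#' @param bone_mask,trabecular_mask logical arrays.
#' @param spacing voxel spacing (mm); output is reported in voxels.
#' @return numeric array (voxels), 0 on bone; all-zero with a warning when
#'   there is no marrow.
#' @export
inter_trabecular_distance_map <- function(bone_mask, trabecular_mask,
                                          spacing = c(1, 1, 1)) {
  if (!any(trabecular_mask)) stop("empty trabecular domain")
  marrow <- trabecular_mask & !bone_mask
  d <- dim(bone_mask)
  if (!any(marrow)) {
    warning("no marrow in the trabecular domain; Tb.1/N map is all zero")
    return(array(0, d))
  }
  lt <- cpp_local_thickness(as.logical(marrow), d, spacing)
  array(lt / spacing[1], d) # report in voxels (isotropic convention)
}

#' Per-voxel strain energy density map from a micro-FE solution
#'
#' @param model an `fe_model`; `result` the matching `fe_result`.
#' @param result the solved `fe_result`.
#' @return numeric array over the model grid: element SED on bone voxels,
#'   0 elsewhere.
#' @export
fe_sed_map <- function(model, result) {
  out <- array(0, model$dim)
  out[model$elements] <- result$sed
  out
}

#' Smooth trabecular voxel maps for the spatial analysis
#'
#' Produces the four trabecular parametric maps on the eroded trabecular
#' domain: homogenized BMD, local bone volume fraction, homogenized
#' inter-trabecular distance, and homogenized SED. The domain is the
#' trabecular mask eroded by `erosion_depth` voxels so that no kernel
#' reaches the cortex; the defaults tie the erosion depth to the kernel
#' radius.
#'
#' @param vol a [bone_volume()].
#' @param seg a `compartment_segmentation`.
#' @param sed_map optional SED array from [fe_sed_map()]; omitted -> no
#'   `h_tb_sed` map.
#' @param radius kernel radius (voxels) for BMD, SED and BV/TV (default 11).
#' @param radius_1n kernel radius for Tb.1/N (default 5).
#' @param erosion_depth erosion of the trabecular domain (voxels); default
#'   equal to `radius`.
#' @return a `voxel_map_set` list of arrays (`h_tb_bmd`, `l_tb_bvtv`,
#'   `h_tb_1n`, optionally `h_tb_sed`), the `domain` mask and parameters.
#' @export
voxel_map_set <- function(vol, seg, sed_map = NULL, radius = 11,
                          radius_1n = 5, erosion_depth = radius) {
  sp <- vol_spacing(vol)
  trab <- seg$trabecular_mask
  domain <- if (erosion_depth > 0) erode_mask(trab, erosion_depth) else trab
  if (!any(domain))
    stop("trabecular domain empty after erosion; reduce erosion_depth")
  tb1n <- inter_trabecular_distance_map(seg$bone_mask, trab, sp)
  maps <- list(
    h_tb_bmd = homogenize(vol_array(vol), trab, radius),
    l_tb_bvtv = local_bvtv(seg$bone_mask & trab, trab, radius),
    h_tb_1n = homogenize(tb1n, trab, radius_1n))
  if (!is.null(sed_map))
    maps$h_tb_sed <- homogenize(sed_map, trab, radius)
  for (nm in names(maps)) maps[[nm]][!domain] <- NA_real_
  structure(c(maps, list(domain = domain, spacing = sp, radius = radius,
                         radius_1n = radius_1n,
                         erosion_depth = erosion_depth)),
            class = "voxel_map_set")
}

#' @export
print.voxel_map_set <- function(x, ...) {
  nm <- intersect(c("h_tb_bmd", "l_tb_bvtv", "h_tb_1n", "h_tb_sed"), names(x))
  cat(sprintf("<voxel_map_set> %s on %d domain voxels (r = %d / %d, erosion %d)\n",
              paste(nm, collapse = ", "), sum(x$domain), x$radius,
              x$radius_1n, x$erosion_depth))
  invisible(x)
}
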