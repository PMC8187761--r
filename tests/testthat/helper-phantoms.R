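# Shared fixture builders. Everything is generated in code; the phantom definitions below
# are the noise-free geometric phantoms the closed-form oracles refer to.

# hollow cylinder: outer radius b, wall thickness th, no interior lattice
hollow_shell_spec <- function(b = 1.8, th = 0.9, grid = c(56, 56, 24),
                              spacing = 0.082) {
  phantom_spec(grid_shape = grid, spacing = spacing, outer_radius_mm = b,
               cortical_thickness_mm = th, taper = 0, noise_sd = 0,
               blur_sigma = 0, trabecular_thickness_mm = 1e-4,
               trabecular_period_mm = 0.8, lattice_kind = "rods")
}

# axial plate lattice with exact thickness/period in voxels
plates_spec <- function(t_vox = 2, p_vox = 10, spacing = 0.05,
                        grid = c(70, 70, 40), outer = 1.6, cortex = 0.3) {
  phantom_spec(grid_shape = grid, spacing = spacing, outer_radius_mm = outer,
               cortical_thickness_mm = cortex, taper = 0,
               trabecular_period_mm = p_vox * spacing,
               trabecular_thickness_mm = t_vox * spacing,
               lattice_kind = "plates", noise_sd = 0, blur_sigma = 0)
}

# ground-truth compartment segmentation of a taper-free phantom
ground_truth_segmentation <- function(spec, vol, bone_threshold = 450) {
  d <- spec$grid_shape
  sp <- rep(spec$spacing, 3)
  cxy <- (d[1:2] - 1) / 2 * sp[1:2]
  r2 <- outer(((1:d[1]) - 1) * sp[1] - cxy[1],
              ((1:d[2]) - 1) * sp[2] - cxy[2],
              function(x, y) x^2 + y^2)
  peri <- sweep(array(r2, d), 3, spec$outer_radius_profile^2, "<=")
  trab <- sweep(array(r2, d), 3,
                (spec$outer_radius_profile -
                 spec$cortical_thickness_profile)^2, "<=")
  attr(peri, "spacing") <- sp
  list(periosteal_mask = peri, trabecular_mask = trab,
       cortical_mask = peri & !trab,
       bone_mask = array(unclass(vol) > bone_threshold, d),
       spacing = sp)
}

# enumerated voxel count of a disk of radius R (centre between voxels)
disk_voxels <- function(n, spacing, R) {
  c0 <- (n - 1) / 2 * spacing
  x <- (seq_len(n) - 1) * spacing - c0
  sum(outer(x, x, function(a, b) sqrt(a^2 + b^2) <= R))
}

# enumerated voxel count of the integer ball ||u|| <= r
ball_voxels <- function(r) {
  m <- ceiling(r)
  g <- expand.grid(x = -m:m, y = -m:m, z = -m:m)
  sum(g$x^2 + g$y^2 + g$z^2 <= r^2 + 1e-9)
}
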