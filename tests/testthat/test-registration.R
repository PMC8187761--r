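cylinder_fixture_for_reg <- function() {
  spec <- hollow_shell_spec(b = 1.4, th = 0.5, grid = c(48, 48, 16))
  vol <- make_phantom(spec)
  seg <- segment_volume(vol)
  list(mesh = periosteal_mesh(seg$periosteal_mask, n_angles = 24),
       seg = seg, spacing = vol_spacing(vol))
}

reg_fixture <- function(seed = 7) {
  set.seed(seed)
  spec <- phantom_spec(grid_shape = c(48, 48, 32), outer_radius_mm = 1.4,
                       noise_sd = 0, blur_sigma = 0)
  vol <- make_phantom(spec)
  seg <- segment_volume(vol)
  list(spec = spec, mask = seg$periosteal_mask,
       spacing = vol_spacing(vol))
}

test_that("self-registration is the identity", {
  f <- reg_fixture()
  tr <- register_to_template(f$mask, f$mask, f$spacing, deformable = FALSE)
  expect_lt(max(abs(tr$affine[1:3, 4])) / f$spacing[1], 0.1)
  expect_lt(max(abs(tr$affine[1:3, 1:3] - diag(3))), 0.01)
})

test_that("a known translation is recovered within half a voxel", {
  # an elliptical tube: a circular phantom leaves in-plane rotation as a
  # flat direction of the metric, so the translation parameters would not
  # be identifiable on it
  d <- c(48, 48, 32)
  spc <- rep(0.082, 3)
  cx <- (d[1] - 1) / 2 * spc[1]
  x <- (seq_len(d[1]) - 1) * spc[1] - cx
  y <- (seq_len(d[2]) - 1) * spc[2] - cx
  mask <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    az <- 1.5 * (1 + 0.1 * (z / d[3] - 0.5))
    mask[, , z] <- outer(x, y, function(a, b) (a / az)^2 + (b / 0.95)^2 <= 1)
  }
  moved <- array(FALSE, d)
  moved[6:48, 4:48, ] <- mask[1:43, 1:45, ]
  tr <- register_to_template(moved, mask, spc, deformable = FALSE)
  expect_lt(abs(tr$affine[1, 4] - 5 * spc[1]), 0.5 * spc[1])
  expect_lt(abs(tr$affine[2, 4] - 3 * spc[2]), 0.5 * spc[2])
  expect_lt(abs(tr$affine[3, 4]), 0.5 * spc[3])
  expect_lt(tr$metric["affine"], tr$metric["initial"])
})

test_that("a small affine plus smooth warp is recovered within a voxel", {
  f <- reg_fixture()
  warped_spec <- f$spec
  warped_spec$outer_radius_profile <- f$spec$outer_radius_profile *
    1.03 * (1 + 0.15 * sin(seq(0, pi, length.out = 32)))
  moved <- segment_volume(make_phantom(warped_spec))$periosteal_mask
  tr <- register_to_template(moved, f$mask, f$spacing, deformable = TRUE,
                             demons_iter = 40)
  sdf_s <- signed_distance(moved, f$spacing)
  sdf_t <- signed_distance(f$mask, f$spacing)
  rs <- resample_to_template(sdf_s, tr)
  band <- abs(sdf_t) < 0.3 & !is.na(rs)
  err_vox <- abs(rs - sdf_t)[band] / f$spacing[1]
  expect_lt(mean(err_vox), 1)
})

test_that("resampling a constant map leaves interior values unchanged", {
  f <- reg_fixture()
  tr <- register_to_template(f$mask, f$mask, f$spacing, deformable = FALSE)
  const <- array(5, dim(f$mask))
  rs <- resample_to_template(const, tr)
  inner <- bonespm:::erode_mask(f$mask, 2)
  inner[, , c(1:3, 30:32)] <- FALSE # axial ends can map out of the grid
  expect_true(all(abs(rs[inner] - 5) < 1e-6))
})

test_that("surface correspondence copies values exactly for identity", {
  f <- cylinder_fixture_for_reg()
  vals <- tibble::tibble(v = sin(seq_len(nrow(f$mesh$vertices))))
  out <- correspond_surfaces(f$mesh, f$mesh, vals, transform = NULL)
  expect_equal(out$v, vals$v, tolerance = 1e-9)
  expect_true(all(out$qc_dist < 1e-9))
  # undefined subject values propagate
  vals$v[5] <- NA
  out2 <- correspond_surfaces(f$mesh, f$mesh, vals, transform = NULL)
  expect_true(is.na(out2$v[5]))
})

test_that("surface correspondence undoes a known translation", {
  f <- cylinder_fixture_for_reg()
  shift <- c(0.2, -0.15, 0)
  sub_mesh <- f$mesh
  sub_mesh$vertices <- sweep(f$mesh$vertices, 2, shift, "+")
  tr <- structure(list(
    affine = rbind(cbind(diag(3), shift), c(0, 0, 0, 1)),
    displacement = list(array(0, c(48, 48, 16)), array(0, c(48, 48, 16)),
                        array(0, c(48, 48, 16))),
    dim = c(48, 48, 16), spacing = f$spacing), class = "subject_transform")
  vals <- tibble::tibble(v = cos(seq_len(nrow(f$mesh$vertices)) / 5))
  out <- correspond_surfaces(sub_mesh, f$mesh, vals, transform = tr)
  expect_equal(out$v, vals$v, tolerance = 1e-6)
})

test_that("shape PCA recovers a single generating mode", {
  set.seed(5)
  base <- cylinder_fixture_for_reg()$mesh
  meshes <- lapply(1:12, function(i) {
    m <- base
    s <- rnorm(1, 1, 0.08)
    m$vertices <- m$vertices * s # one pure size mode
    m
  })
  sc <- shape_pca(meshes)
  expect_gte(sc$variance_explained[1], 0.9)
  expect_lt(max(abs(colMeans(as.matrix(sc$scores)))), 1e-8)
  # duplicated subjects get identical scores
  meshes2 <- c(meshes[1:6], meshes[1:6])
  sc2 <- shape_pca(meshes2)
  expect_equal(as.matrix(sc2$scores)[1:6, ], as.matrix(sc2$scores)[7:12, ],
               tolerance = 1e-8)
  expect_error(shape_pca(meshes[1]), "at least two")
})

test_that("template defaults to the median-size subject and is deterministic", {
  set.seed(6)
  masks <- lapply(c(0.9, 1.0, 1.15), function(s) {
    spec <- hollow_shell_spec(b = 1.3 * s, th = 0.5,
                              grid = c(48, 48, 12))
    segment_volume(make_phantom(spec))$periosteal_mask
  })
  t1 <- build_template(masks, rep(0.082, 3))
  t2 <- build_template(masks, rep(0.082, 3))
  expect_equal(t1$reference, 2) # the median-volume subject
  expect_identical(t1$mask, t2$mask)
  expect_error(build_template(list(), rep(0.082, 3)), "empty")
  # single-subject cohort: the template is that subject
  t3 <- build_template(masks[1], rep(0.082, 3))
  expect_identical(as.logical(t3$mask), as.logical(masks[[1]]))
})

test_that("mean-shape refinement lands between two mirrored perturbations", {
  base <- hollow_shell_spec(b = 1.3, th = 0.5, grid = c(48, 48, 16))
  # a mid-shaft bulge vs waist: mirrored, and not mapped onto each other by
  # any affine (a full-period sinusoid would be, via a half-period shift)
  pert <- 0.06 * sin(seq(0, pi, length.out = 16))
  up <- base; up$outer_radius_profile <- base$outer_radius_profile * (1 + pert)
  dn <- base; dn$outer_radius_profile <- base$outer_radius_profile * (1 - pert)
  masks <- lapply(list(up, dn), function(s)
    segment_volume(make_phantom(s))$periosteal_mask)
  tmpl <- build_template(masks, rep(0.082, 3), refine_iter = 1)
  ref_mask <- segment_volume(make_phantom(base))$periosteal_mask
  dice <- 2 * sum(tmpl$mask & ref_mask) / (sum(tmpl$mask) + sum(ref_mask))
  expect_gt(dice, 0.95)
})
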