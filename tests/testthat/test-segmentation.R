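test_that("periosteal mask of a solid cylinder matches the analytic disk", {
  spec <- phantom_spec(grid_shape = c(48, 48, 16), outer_radius_mm = 1.5,
                       cortical_thickness_mm = 1.45, taper = 0,
                       noise_sd = 0, blur_sigma = 0,
                       trabecular_thickness_mm = 1e-4,
                       trabecular_period_mm = 0.8, lattice_kind = "rods")
  vol <- make_phantom(spec)
  peri <- find_periosteal_surface(vol)
  per_slice <- apply(peri, 3, sum)
  analytic <- disk_voxels(48, 0.082, 1.5)
  ring <- disk_voxels(48, 0.082, 1.5 + 0.082) - disk_voxels(48, 0.082,
                                                            1.5 - 0.082)
  expect_true(all(abs(per_slice - analytic) <= ring))
})

test_that("an all-marrow volume raises an empty-segmentation error", {
  vol <- bone_volume(array(30, c(16, 16, 8)), 0.082)
  expect_error(find_periosteal_surface(vol, threshold = 300),
               "empty segmentation")
})

test_that("interior lattice gaps are filled in the periosteal mask", {
  base <- phantom_spec(grid_shape = c(48, 48, 16), outer_radius_mm = 1.5,
                       cortical_thickness_mm = 0.4, taper = 0, noise_sd = 0,
                       blur_sigma = 0)
  solid <- base
  solid$cortical_thickness_profile <- rep(1.45, 16)
  m_lattice <- find_periosteal_surface(make_phantom(base), threshold = 300)
  m_solid <- find_periosteal_surface(make_phantom(solid), threshold = 300)
  expect_identical(as.logical(m_lattice), as.logical(m_solid))
})

test_that("cortical shell thickness is recovered within half a voxel", {
  spec <- hollow_shell_spec(b = 1.8, th = 0.9)
  vol <- make_phantom(spec)
  seg <- segment_volume(vol)
  lt <- bonespm:::cpp_local_thickness(as.logical(seg$cortical_mask), dim(vol),
                            vol_spacing(vol))
  # centre-to-centre sphere diameters exceed the physical wall by one voxel
  measured <- mean(lt[seg$cortical_mask]) - 0.082
  expect_lt(abs(measured - 0.9), 0.041)
  # hollow shell: no trabecular bone at all
  expect_equal(sum(seg$bone_mask & seg$trabecular_mask), 0)
})

test_that("a sub-pore-scale cortical breach leaves the cortical mask intact", {
  spec <- hollow_shell_spec(b = 1.5, th = 0.6, grid = c(48, 48, 12))
  vol <- make_phantom(spec)
  vol2 <- vol
  # poke a single-voxel pore through the shell at mid-height
  d <- dim(vol)
  mid <- d[3] %/% 2
  shell_vox <- which(unclass(vol)[, , mid] > 450, arr.ind = TRUE)
  pick <- shell_vox[which.max(shell_vox[, 1]), ]
  vol2[pick[1], pick[2], mid] <- 30
  seg1 <- segment_volume(vol, threshold = 300, bone_threshold = 450)
  seg2 <- segment_volume(vol2, threshold = 300, bone_threshold = 450)
  expect_identical(as.logical(seg1$cortical_mask),
                   as.logical(seg2$cortical_mask))
})

test_that("compartments partition the periosteal mask without overlap", {
  spec <- phantom_spec(grid_shape = c(48, 48, 24), outer_radius_mm = 1.5)
  vol <- make_phantom(spec)
  seg <- segment_volume(vol)
  expect_equal(sum(seg$cortical_mask & seg$trabecular_mask), 0)
  expect_true(all(seg$periosteal_mask[seg$cortical_mask]))
  expect_true(all(seg$periosteal_mask[seg$trabecular_mask]))
  expect_true(all(seg$membership >= 0 & seg$membership <= 1))
  expect_true(all(seg$membership[!seg$periosteal_mask] == 0))
})

test_that("s-shaped membership matches its closed form", {
  expect_equal(s_membership(400, 400, 800), 0)
  expect_equal(s_membership(800, 400, 800), 1)
  expect_equal(s_membership(600, 400, 800), 0.5)
  expect_equal(s_membership(500, 400, 800), 2 * (100 / 400)^2) # 0.125
  expect_error(s_membership(1, 5, 5), "a < b")
  # monotone and scale-invariant
  x <- seq(300, 900, by = 7)
  expect_true(all(diff(s_membership(x, 400, 800)) >= 0))
  expect_equal(s_membership(2 * x, 800, 1600), s_membership(x, 400, 800))
})

test_that("NL-FCM separates well-separated clusters exactly at lambda = 0", {
  d <- c(12, 12, 12)
  half <- array(rep(c(FALSE, TRUE), each = prod(d) / 2), d)
  vol <- bone_volume(array(ifelse(half, 10, 0), d), 0.1)
  pdist <- array(ifelse(half, 2, 0.2), d)
  res <- nlfcm_endosteal(vol, half, array(TRUE, d), pdist, lambda = 0)
  expect_true(res$converged)
  # hard labels equal the construction for every voxel; cluster identity by
  # periosteal distance (cortical = near side)
  expect_identical(as.logical(res$cortical_mask), as.logical(!half))
  # objective non-increasing across iterations
  expect_true(all(diff(res$objective) <= 1e-9 * max(res$objective)))
})

test_that("NL-FCM memberships harden as the fuzzifier decreases", {
  set.seed(4)
  d <- c(8, 8, 8)
  vol <- bone_volume(array(rnorm(prod(d), rep(c(0, 4), each = 256), 1), d),
                     0.1)
  bm <- array(rep(c(FALSE, TRUE), each = 256), d)
  pd <- array(rep(c(0.2, 2), each = 256), d)
  maxm <- vapply(c(3, 2, 1.3), function(m) {
    r <- nlfcm_endosteal(vol, bm, array(TRUE, d), pd, fuzzifier = m,
                         lambda = 0)
    mean(pmax(r$membership_cortical, 1 - r$membership_cortical))
  }, numeric(1))
  expect_true(all(diff(maxm) > 0))
})

test_that("NL-FCM flags degenerate identical-feature input", {
  d <- c(8, 8, 8)
  res <- nlfcm_endosteal(bone_volume(array(1, d), 0.1), array(TRUE, d),
                         array(TRUE, d), array(1, d), lambda = 0)
  expect_true(res$degenerate)
  expect_false(res$converged)
})

test_that("the non-local term regularizes salt-and-pepper memberships", {
  set.seed(8)
  d <- c(10, 10, 10)
  base <- array(rep(c(0, 4), each = 500), d)
  noisy <- base + rnorm(prod(d), 0, 2.2)
  vol <- bone_volume(noisy, 0.1)
  bm <- array(rep(c(FALSE, TRUE), each = 500), d)
  pd <- array(rep(c(0.2, 2), each = 500), d)
  err <- vapply(c(0, 0.8), function(l) {
    r <- nlfcm_endosteal(vol, bm, array(TRUE, d), pd, lambda = l)
    mean(as.logical(r$cortical_mask) != as.logical(pd < 1))
  }, numeric(1))
  expect_lte(err[2], err[1])
})
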