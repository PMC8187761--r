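beam_model <- function(nx = 8, ny = 8, nz = 12, h = 0.1, ...) {
  build_fe_model(list(bone_mask = array(TRUE, c(nx, ny, nz))),
                 spacing = rep(h, 3), ...)
}

test_that("model building counts elements, nodes and floating voxels", {
  m <- build_fe_model(list(bone_mask = array(TRUE, c(10, 10, 10))),
                      spacing = c(0.1, 0.1, 0.1))
  expect_equal(nrow(m$elements), 1000)
  expect_equal(m$n_nodes, 11^3)
  expect_equal(m$n_removed, 0)
  # floating voxel is pruned and counted
  mask <- array(FALSE, c(8, 8, 8))
  mask[2:5, 2:5, ] <- TRUE
  mask[8, 8, 4] <- TRUE
  m2 <- build_fe_model(list(bone_mask = mask), spacing = rep(0.1, 3))
  expect_equal(m2$n_removed, 1)
  # two disjoint spanning columns are both kept
  mask3 <- array(FALSE, c(8, 8, 8))
  mask3[2, 2, ] <- TRUE
  mask3[6, 6, ] <- TRUE
  m3 <- build_fe_model(list(bone_mask = mask3), spacing = rep(0.1, 3))
  expect_equal(nrow(m3$elements), 16)
  # two blocks that never meet axially: unsolvable
  mask5 <- array(FALSE, c(8, 8, 8))
  mask5[2:3, 2:3, 1:4] <- TRUE
  mask5[6:7, 6:7, 5:8] <- TRUE
  expect_error(build_fe_model(list(bone_mask = mask5),
                              spacing = rep(0.1, 3)), "unsolvable")
})

test_that("uniaxial beam matches E*A/L stiffness and 0.5*E*eps^2 SED", {
  model <- beam_model(8, 8, 12, h = 0.1)
  res <- solve_compression(model)
  A <- (8 * 0.1)^2
  L <- 12 * 0.1
  expect_equal(res$stiffness, 6829 * A / L, tolerance = 0.01)
  expect_equal(mean(res$sed), 0.5 * 6829 * 0.01^2, tolerance = 0.01)
  expect_lt(max(abs(res$sed - 0.34145)) / 0.34145, 0.01)
  expect_lt(res$force_balance, 1e-4)
  expect_equal(res$energy_balance, 1, tolerance = 1e-4)
  # failure load: uniform strain 1 % vs 0.7 % critical -> 0.7 x reaction
  expect_equal(failure_load(res, model), 0.7 * res$reaction_force,
               tolerance = 1e-4)
  expect_equal(failure_load(res, model, critical_volume_fraction = 1),
               0.7 * res$reaction_force, tolerance = 1e-4)
})

test_that("solution is linear in the applied strain; failure load is not", {
  m1 <- beam_model(6, 6, 9, h = 0.1, applied_strain = 0.01)
  m2 <- beam_model(6, 6, 9, h = 0.1, applied_strain = 0.02)
  r1 <- solve_compression(m1)
  r2 <- solve_compression(m2)
  expect_equal(r2$reaction_force, 2 * r1$reaction_force, tolerance = 1e-5)
  expect_equal(max(abs(r2$displacements - 2 * r1$displacements)), 0,
               tolerance = 1e-6)
  expect_equal(failure_load(r2, m2), failure_load(r1, m1),
               tolerance = 1e-5)
  # zero strain: all-zero solution
  m0 <- beam_model(6, 6, 9, h = 0.1, applied_strain = 0)
  r0 <- solve_compression(m0)
  expect_equal(r0$reaction_force, 0)
  expect_equal(max(abs(r0$displacements)), 0)
  expect_equal(max(r0$sed), 0)
})

test_that("iterative solution matches a dense direct solve on small models", {
  set.seed(2)
  mask <- array(runif(4 * 4 * 5) < 0.9, c(4, 4, 5))
  mask[, , c(1, 5)] <- TRUE
  model <- build_fe_model(list(bone_mask = mask), spacing = rep(0.1, 3))
  res <- solve_compression(model, tol = 1e-10)
  K <- bonespm:::assemble_stiffness(model)
  ndof <- 3L * model$n_nodes
  kz <- model$node_grid[, "k"]
  fixed <- logical(ndof)
  zdof <- function(sel) 3L * (which(sel) - 1L) + 3L
  bottom <- kz == (model$zmin - 1L)
  top <- kz == model$zmax
  fixed[zdof(bottom)] <- TRUE
  fixed[zdof(top)] <- TRUE
  u <- numeric(ndof)
  L <- (model$zmax - model$zmin + 1L) * 0.1
  u[zdof(top)] <- -0.01 * L
  free <- !fixed
  Kff <- as.matrix(K[free, free])
  b <- -as.numeric(K[free, fixed] %*% u[fixed])
  # the free system is singular (lateral rigid modes); use the
  # pseudo-inverse for the reference solution
  u_direct <- MASS::ginv(Kff) %*% b
  # compare reactions, which are invariant to the null-space component
  u2 <- u
  u2[free] <- u_direct
  reac_direct <- as.numeric(K %*% u2)
  reac_cg <- as.numeric(K %*% res$displacements)
  expect_equal(sum(reac_cg[zdof(top)]), sum(reac_direct[zdof(top)]),
               tolerance = 1e-8)
})

test_that("beam stiffness is stable under mesh refinement", {
  coarse <- solve_compression(beam_model(4, 4, 8, h = 0.2))
  fine <- solve_compression(beam_model(8, 8, 16, h = 0.1))
  expect_lt(abs(fine$stiffness - coarse$stiffness) / coarse$stiffness,
            0.02)
})

test_that("laterally pinned ends stiffen the beam above E*A/L", {
  free <- solve_compression(beam_model(8, 8, 12, h = 0.1,
                                       lateral = "free"))
  pinned <- solve_compression(beam_model(8, 8, 12, h = 0.1,
                                         lateral = "pinned"))
  expect_gt(pinned$stiffness, free$stiffness)
})

test_that("SED map places element energies on the bone voxels", {
  mask <- array(FALSE, c(6, 6, 8))
  mask[2:5, 2:5, ] <- TRUE
  model <- build_fe_model(list(bone_mask = mask), spacing = rep(0.1, 3))
  res <- solve_compression(model)
  sed <- fe_sed_map(model, res)
  expect_equal(dim(sed), dim(mask))
  expect_true(all(sed[!mask] == 0))
  expect_equal(sum(sed > 0), nrow(model$elements))
})
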