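# Laplace potential, periosteal mesh, streamlines and surface aggregates

cylinder_fixture <- function(b = 1.8, th = 1.0, grid = c(56, 56, 24)) {
  spec <- hollow_shell_spec(b = b, th = th, grid = grid)
  vol <- make_phantom(spec)
  seg <- segment_volume(vol)
  list(spec = spec, vol = vol, seg = seg, spacing = vol_spacing(vol))
}

test_that("Laplace potential matches the annulus closed form mid-wall", {
  f <- cylinder_fixture()
  lap <- solve_laplace_cortex(f$seg)
  expect_true(lap$converged)
  d <- dim(f$vol)
  cx <- (d[1] - 1) / 2 * f$spacing[1]
  idx <- which(lap$domain, arr.ind = TRUE)
  r <- sqrt(((idx[, 1] - 1) * f$spacing[1] - cx)^2 +
            ((idx[, 2] - 1) * f$spacing[2] - cx)^2)
  # the Dirichlet bands sit half a voxel outside each surface
  hv <- f$spacing[1] / 2
  b_eff <- 1.8 + hv
  a_eff <- 0.8 - hv
  mid <- abs(r - 1.3) < 0.06
  phi_num <- lap$potential[lap$domain][mid]
  phi_true <- log(r[mid] / b_eff) / log(a_eff / b_eff)
  expect_lt(max(abs(phi_num - phi_true)), 0.01)
  # maximum principle: interior strictly inside (0, 1)
  expect_true(all(lap$potential[lap$domain] > 0 &
                  lap$potential[lap$domain] < 1))
})

test_that("Laplace potential across a slab is a linear ramp", {
  d <- c(30, 16, 16)
  domain <- array(FALSE, d)
  domain[11:20, , ] <- TRUE
  peri <- array(FALSE, d)
  peri[11:30, , ] <- TRUE # interior side = x > 20
  attr(peri, "spacing") <- rep(0.1, 3)
  seg <- list(cortical_mask = domain, periosteal_mask = peri)
  lap <- solve_laplace_cortex(seg)
  phi_x <- apply(lap$potential[11:20, , ], 1, mean)
  expected <- seq_len(10) / 11 # linear between the band centres
  expect_lt(max(abs(phi_x - expected)), 0.02)
})

test_that("the periosteal mesh samples the true outer surface", {
  f <- cylinder_fixture()
  mesh <- periosteal_mesh(f$seg$periosteal_mask, n_angles = 32)
  d <- dim(f$vol)
  cx <- (d[1] - 1) / 2 * f$spacing[1]
  vr <- sqrt((mesh$vertices[, 1] - cx)^2 + (mesh$vertices[, 2] - cx)^2)
  expect_lt(max(abs(vr - 1.8)), 0.06)
  expect_equal(nrow(mesh$faces), 2 * 32 * (length(mesh$slices) - 1))
})

test_that("streamline lengths recover the cylinder wall thickness", {
  f <- cylinder_fixture(th = 1.0)
  lap <- solve_laplace_cortex(f$seg)
  mesh <- periosteal_mesh(f$seg$periosteal_mask, n_angles = 32)
  str <- trace_streamlines(lap, mesh, f$spacing)
  expect_gte(mean(str$ok), 0.95)
  err <- abs(str$arc_length - 1.0)
  expect_gte(mean(err <= f$spacing[1] / 2, na.rm = TRUE), 0.95)
})

test_that("slab streamlines are straight with length equal to thickness", {
  d <- c(30, 20, 20)
  domain <- array(FALSE, d)
  domain[11:20, , ] <- TRUE
  peri <- array(FALSE, d)
  peri[11:30, , ] <- TRUE
  attr(peri, "spacing") <- rep(0.1, 3)
  seg <- list(cortical_mask = domain, periosteal_mask = peri)
  lap <- solve_laplace_cortex(seg)
  # seed on the outer face (x = voxel 10.5 boundary -> 0.95 mm), interior
  seeds <- cbind(0.96, seq(0.6, 1.2, by = 0.1), seq(0.6, 1.2, by = 0.1))
  mesh <- list(vertices = seeds)
  str <- trace_streamlines(lap, mesh, rep(0.1, 3))
  expect_true(all(str$ok))
  # wall spans voxels 11..20 -> 1.0 mm
  expect_true(all(abs(str$arc_length - 1.0) < 0.06))
  # straight: lateral drift below a voxel
  for (p in str$points) {
    expect_lt(max(abs(p[, 2] - p[1, 2])), 0.1)
    expect_lt(max(abs(p[, 3] - p[1, 3])), 0.1)
  }
})

test_that("streamlines do not cross each other", {
  f <- cylinder_fixture(grid = c(40, 40, 12), b = 1.3, th = 0.6)
  lap <- solve_laplace_cortex(f$seg)
  mesh <- periosteal_mesh(f$seg$periosteal_mask, n_angles = 16)
  str <- trace_streamlines(lap, mesh, f$spacing)
  # pairwise minimum distance between distinct streamlines in the same
  # slice stays positive (radial field: no crossings)
  z0 <- mesh$vertices[1, 3]
  ring <- which(abs(mesh$vertices[, 3] - z0) < 1e-9 & str$ok)
  for (i in ring[1:4]) for (j in ring[(length(ring) - 3):length(ring)]) {
    if (i >= j) next
    pi <- str$points[[i]]
    pj <- str$points[[j]]
    dd <- outer(seq_len(nrow(pi)), seq_len(nrow(pj)), function(a, b)
      sqrt((pi[a, 1] - pj[b, 1])^2 + (pi[a, 2] - pj[b, 2])^2 +
           (pi[a, 3] - pj[b, 3])^2))
    expect_gt(min(dd), 1e-6)
  }
})

test_that("surface aggregates integrate membership and average maps", {
  f <- cylinder_fixture(th = 1.0)
  lap <- solve_laplace_cortex(f$seg)
  mesh <- periosteal_mesh(f$seg$periosteal_mask, n_angles = 24)
  str <- trace_streamlines(lap, mesh, f$spacing)
  d <- dim(f$vol)
  ones <- array(1, d)
  agg1 <- surface_aggregates(str, ones, ones * 900, spacing = f$spacing)
  # unit membership: SIT equals the arc length by the same quadrature
  expect_equal(agg1$surf_ct_sit, agg1$surf_app_ct_th, tolerance = 1e-9)
  expect_true(all(abs(agg1$surf_ct_bmd - 900) < 1e-6, na.rm = TRUE))
  agg05 <- surface_aggregates(str, ones * 0.5, ones * 900,
                              spacing = f$spacing)
  expect_equal(agg05$surf_ct_sit, 0.5 * agg05$surf_app_ct_th,
               tolerance = 1e-9)
  # real membership never exceeds 1: SIT <= apparent thickness
  agg <- surface_aggregates(str, f$seg$membership, unclass(f$vol),
                            spacing = f$spacing)
  expect_true(all(agg$surf_ct_sit <= agg$surf_app_ct_th + 1e-9,
                  na.rm = TRUE))
})

test_that("cortical thickness tracks from streamlines and standard metrics", {
  # the annular mean thickness (volume / outer area) relates to the radial
  # wall thickness t by a factor (1 - t/2b); apply it before comparing
  f <- cylinder_fixture(th = 0.5)
  sm <- surface_map_set(f$vol, f$seg, n_angles = 24)
  ct <- cortical_metrics(f$vol, f$seg)
  arc <- mean(sm$values$surf_app_ct_th, na.rm = TRUE)
  annular_from_arc <- arc * (1 - arc / (2 * 1.8))
  expect_lt(abs(annular_from_arc - ct$ct_th) / ct$ct_th, 0.05)
})

test_that("PLY files round-trip vertices, values and faces", {
  mesh <- list(vertices = matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, 3,
                                 byrow = TRUE),
               faces = matrix(c(1L, 2L, 3L), 1, 3))
  vals <- data.frame(surf_app_ct_th = c(0.5, 0.7, NA))
  path <- tempfile(fileext = ".ply")
  write_surface_ply(mesh, vals, path)
  raw <- readBin(path, "raw", file.size(path))
  marker <- charToRaw("end_header\n")
  pos <- NA
  for (i in seq_len(length(raw) - length(marker) + 1))
    if (all(raw[i:(i + length(marker) - 1)] == marker)) { pos <- i; break }
  hdr <- strsplit(rawToChar(raw[1:(pos - 1)]), "\n")[[1]]
  expect_true("format binary_little_endian 1.0" %in% hdr)
  expect_true("property float surf_app_ct_th" %in% hdr)
  payload <- raw[(pos + length(marker)):length(raw)]
  v <- readBin(payload, "numeric", n = 12, size = 4, endian = "little")
  m <- matrix(v, 3, 4, byrow = TRUE)
  expect_equal(m[, 1:3], mesh$vertices, tolerance = 1e-6)
  expect_equal(m[1:2, 4], c(0.5, 0.7), tolerance = 1e-6)
  expect_true(is.nan(m[3, 4]))
  rest <- payload[-(1:48)]
  expect_equal(as.integer(rest[1]), 3L)
  f0 <- readBin(rest[-1], "integer", 3, size = 4, endian = "little")
  expect_equal(f0, c(0L, 1L, 2L))
  unlink(path)
})
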