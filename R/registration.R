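# Spatial normalization to a common template. The registration metric is
# the squared difference of signed distance maps of the periosteal masks:
# synthetic and real intensity distributions differ, but the geometry of the
# periosteal surface is exactly the correspondence the analysis needs.

#' Signed distance map of a mask
#'
#' Positive outside, negative inside, in mm.
#' @param mask logical array.
#' @param spacing voxel spacing (mm).
#' @return numeric array.
#' @export
signed_distance <- function(mask, spacing) {
  d <- dim(mask)
  dist_in <- cpp_edt3d(as.logical(mask), d, spacing)
  dist_out <- cpp_edt3d(as.logical(!mask), d, spacing)
  array(dist_out - dist_in, d)
}

# affine parameter vector -> 4x4 matrix (world mm coordinates)
# theta: translation (3), rotation xyz (3), log-scale (1 or 3), shear (0 or 3)
affine_from_params <- function(theta, kind = c("similarity", "affine")) {
  kind <- match.arg(kind)
  t <- theta[1:3]
  r <- theta[4:6]
  Rx <- rbind(c(1, 0, 0), c(0, cos(r[1]), -sin(r[1])),
              c(0, sin(r[1]), cos(r[1])))
  Ry <- rbind(c(cos(r[2]), 0, sin(r[2])), c(0, 1, 0),
              c(-sin(r[2]), 0, cos(r[2])))
  Rz <- rbind(c(cos(r[3]), -sin(r[3]), 0), c(sin(r[3]), cos(r[3]), 0),
              c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  if (kind == "similarity") {
    S <- diag(3) * exp(theta[7])
  } else {
    S <- diag(exp(theta[7:9]))
    Sh <- diag(3)
    Sh[1, 2] <- theta[10]; Sh[1, 3] <- theta[11]; Sh[2, 3] <- theta[12]
    S <- S %*% Sh
  }
  A <- diag(4)
  A[1:3, 1:3] <- R %*% S
  A[1:3, 4] <- t
  A
}

world_coords <- function(idx, spacing) {
  sweep(idx - 1, 2, spacing, "*")
}

# sample a field (array) at world coordinates via trilinear interpolation
sample_world <- function(arr, coords_mm, spacing, fill = NA_real_) {
  cpp_trilinear(as.numeric(arr), dim(arr),
                sweep(coords_mm, 2, spacing, "/"), fill)
}

# optimise an affine stage: minimise mean squared sdf difference over
# template sample points
fit_affine_stage <- function(sdf_t, sdf_s, spacing, pts_mm, init, kind) {
  centre <- colMeans(pts_mm)
  # points mapped off the subject grid pay a graded charge: large enough
  # that pushing points off-grid cannot mimic a good fit, small enough not
  # to veto genuine transforms whose band caps leave the field of view
  miss2 <- 0.1 * (8 * min(spacing))^2
  obj <- function(theta) {
    A <- affine_from_params(theta, kind)
    # rotate/scale about the point-cloud centre, not the grid origin
    p <- sweep(pts_mm, 2, centre)
    q <- p %*% t(A[1:3, 1:3])
    q <- sweep(q, 2, centre + A[1:3, 4], "+")
    v <- sample_world(sdf_s, q, spacing, fill = NA_real_)
    tv <- attr(pts_mm, "target")
    sq <- (v - tv)^2
    sq[is.na(sq)] <- miss2
    mean(sq)
  }
  fit <- optim(init, obj, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-8))
  # restart once: Nelder-Mead simplices collapse in flat valleys
  fit <- optim(fit$par, obj, method = "Nelder-Mead",
               control = list(maxit = 300, reltol = 1e-9))
  list(par = fit$par, value = fit$value, value_init = obj(init),
       centre = centre, kind = kind)
}

# full affine (4x4, acting on centred coordinates) from a stage fit
stage_matrix <- function(fit) {
  A <- affine_from_params(fit$par, fit$kind)
  # convert "about centre" to plain world-coordinate affine
  M <- diag(4)
  M[1:3, 1:3] <- A[1:3, 1:3]
  M[1:3, 4] <- fit$centre + A[1:3, 4] - A[1:3, 1:3] %*% fit$centre
  M
}

#' Register a subject to a template
#'
#' Similarity then full affine stage, then a multi-resolution demons-style
#' deformable stage, all driven by the squared difference of the periosteal
#' signed distance maps. The returned transform maps template world
#' coordinates to subject world coordinates (a pull-back: resampling uses it
#' directly).
#'
#' @param subject_mask,template_mask periosteal masks (same grid/spacing).
#' @param spacing voxel spacing (mm).
#' @param deformable run the deformable stage.
#' @param demons_iter deformable-stage iterations.
#' @param demons_sigma smoothing (voxels) of the displacement field.
#' @return a `subject_transform`: `affine` (4x4), `displacement` (list of 3
#'   arrays, mm, on the template grid), metric trace, and the final metric.
#' @export
register_to_template <- function(subject_mask, template_mask, spacing,
                                 deformable = TRUE, demons_iter = 30,
                                 demons_sigma = 2) {
  d <- dim(template_mask)
  sdf_t <- signed_distance(template_mask, spacing)
  sdf_s <- signed_distance(subject_mask, spacing)
  # sample points: template voxels within a band of the surface
  band <- which(abs(sdf_t) < 8 * min(spacing))
  if (length(band) > 10000) band <- band[seq(1, length(band), length.out = 10000)]
  idx <- arrayInd(band, d)
  pts <- world_coords(idx, spacing)
  attr(pts, "target") <- sdf_t[band]
  metric0 <- mean((sample_world(sdf_s, pts, spacing) -
                   sdf_t[band])^2, na.rm = TRUE)
  fit1 <- fit_affine_stage(sdf_t, sdf_s, spacing, pts,
                           init = rep(0, 7), kind = "similarity")
  init2 <- c(fit1$par[1:6], rep(fit1$par[7], 3), rep(0, 3))
  fit2 <- fit_affine_stage(sdf_t, sdf_s, spacing, pts,
                           init = init2, kind = "affine")
  best <- if (fit2$value <= fit1$value) fit2 else fit1
  affine <- stage_matrix(best)
  metric_affine <- best$value
  # compare on the stage's own objective (the identity is a simplex vertex,
  # so this can only trip on a genuine failure, not on rounding)
  if (metric_affine > fit1$value_init * (1 + 1e-6) + 1e-12)
    stop(sprintf("affine stage worsened the metric (%.4g -> %.4g)",
                 fit1$value_init, metric_affine))
  # deformable stage on the affinely-resampled moving sdf
  disp <- list(array(0, d), array(0, d), array(0, d))
  metric_def <- metric_affine
  if (deformable) {
    grid_idx <- arrayInd(seq_len(prod(d)), d)
    grid_mm <- world_coords(grid_idx, spacing)
    warped0 <- array(sample_world(sdf_s, apply_affine(affine, grid_mm),
                                  spacing, fill = NA_real_), d)
    # clamp the distance maps (far-field values otherwise dominate the
    # residual) and smooth them lightly: the discrete EDT is bumpy at the
    # voxel scale and demons would chase that noise
    cap <- 8 * min(spacing)
    clamp <- function(x) pmin(pmax(x, -cap), cap)
    smooth_sdf <- function(x)
      vol_array(gaussian_blur(bone_volume(x, spacing), 1.5 * min(spacing)))
    fixed <- smooth_sdf(clamp(sdf_t))
    valid <- array(!is.na(warped0), d)
    moving <- warped0
    moving[!valid] <- cap
    moving <- smooth_sdf(clamp(moving))
    # judge the stage on the surface band, clear of invalid-data bleed
    band_mask <- abs(sdf_t) < 4 * min(spacing) & erode_mask(valid, 3)
    if (!any(band_mask)) band_mask <- abs(sdf_t) < 4 * min(spacing)
    band_metric <- function(mv) mean(abs(mv - fixed)[band_mask])
    metric_affine_band <- band_metric(moving)
    u <- disp
    for (it in seq_len(demons_iter)) {
      pos <- grid_mm
      pos[, 1] <- pos[, 1] + as.numeric(u[[1]])
      pos[, 2] <- pos[, 2] + as.numeric(u[[2]])
      pos[, 3] <- pos[, 3] + as.numeric(u[[3]])
      mv <- array(sample_world(moving, pos, spacing, fill = cap), d)
      r <- mv - fixed
      r[!valid] <- 0
      g <- array_gradient(mv, spacing)
      gn2 <- g[[1]]^2 + g[[2]]^2 + g[[3]]^2
      den <- gn2 + r^2
      den[den < 1e-9] <- 1e-9
      step_cap <- min(spacing)
      for (k in 1:3) {
        du <- -r * g[[k]] / den
        du <- pmin(pmax(du, -step_cap), step_cap)
        u[[k]] <- gaussian_blur(bone_volume(u[[k]] + du, spacing),
                                demons_sigma * min(spacing))
        u[[k]] <- vol_array(u[[k]])
      }
    }
    pos <- grid_mm
    for (k in 1:3) pos[, k] <- pos[, k] + as.numeric(u[[k]])
    mv <- array(sample_world(moving, pos, spacing, fill = cap), d)
    metric_def <- band_metric(mv)
    accepted <- metric_def <= metric_affine_band
    if (accepted) {
      disp <- u
    } else {
      metric_def <- metric_affine_band # keep affine-only result
    }
    metric_band <- c(affine_band = metric_affine_band,
                     deformable_band = metric_def)
  }
  if (!deformable) metric_band <- c(affine_band = NA_real_,
                                    deformable_band = NA_real_)
  structure(list(affine = affine, displacement = disp, dim = d,
                 spacing = spacing,
                 metric = c(initial = metric0, affine = metric_affine,
                            metric_band)),
            class = "subject_transform")
}

apply_affine <- function(A, pts_mm) {
  q <- pts_mm %*% t(A[1:3, 1:3])
  sweep(q, 2, A[1:3, 4], "+")
}

# central-difference gradient of a 3D array, mm units
array_gradient <- function(a, spacing) {
  g <- vector("list", 3)
  for (k in 1:3) {
    o <- c(0L, 0L, 0L); o[k] <- 1L
    fwd <- shift_array(a, o)
    bwd <- shift_array(a, -o)
    gk <- (fwd - bwd) / (2 * spacing[k])
    gk[is.na(gk)] <- 0
    g[[k]] <- gk
  }
  g
}

#' Map template-grid coordinates through a subject transform
#'
#' @param transform a `subject_transform`.
#' @param pts_mm n x 3 template world coordinates.
#' @return n x 3 subject world coordinates.
#' @export
transform_points <- function(transform, pts_mm) {
  # total map: affine(x) evaluated at x + u(x) happens on the sdf; for
  # resampling we compose: subject coordinate = A(x) sampled after the
  # displacement; displacement is stored on the template grid in mm
  u <- vapply(1:3, function(k)
    sample_world(transform$displacement[[k]], pts_mm, transform$spacing,
                 fill = 0), numeric(nrow(pts_mm)))
  apply_affine(transform$affine, pts_mm + u)
}

#' Resample a subject voxel map onto the template grid
#'
#' Trilinear interpolation with undefined-flag (`NA`) propagation.
#'
#' @param map subject-space array (`NA` = undefined).
#' @param transform a `subject_transform` from [register_to_template()].
#' @return array on the template grid.
#' @export
resample_to_template <- function(map, transform) {
  d <- transform$dim
  grid_mm <- world_coords(arrayInd(seq_len(prod(d)), d), transform$spacing)
  pos <- transform_points(transform, grid_mm)
  array(sample_world(map, pos, transform$spacing, fill = NA_real_), d)
}

#' Carry subject per-vertex surface values to the template mesh
#'
#' Each template vertex is mapped through the transform into subject space
#' and its value interpolated barycentrically on the nearest face of the
#' subject mesh; the distance to that face is logged as QC and vertices
#' beyond `max_dist` are undefined-flagged.
#'
#' @param subject_mesh,template_mesh `surface_mesh` objects.
#' @param subject_values data frame of per-vertex values on the subject
#'   mesh.
#' @param transform a `subject_transform` (or `NULL` for identity).
#' @param max_dist QC threshold in mm.
#' @return tibble of per-template-vertex values plus `qc_dist`.
#' @export
correspond_surfaces <- function(subject_mesh, template_mesh, subject_values,
                                transform = NULL, max_dist = 1) {
  tv <- template_mesh$vertices
  pts <- if (is.null(transform)) tv else transform_points(transform, tv)
  sv <- subject_mesh$vertices
  faces <- subject_mesh$faces
  # face adjacency per vertex
  vf <- vector("list", nrow(sv))
  for (f in seq_len(nrow(faces)))
    for (v in faces[f, ]) vf[[v]] <- c(vf[[v]], f)
  vals <- as.matrix(subject_values)
  out <- matrix(NA_real_, nrow(tv), ncol(vals))
  qc <- numeric(nrow(tv))
  # nearest subject vertex (chunked brute force)
  nn <- integer(nrow(tv))
  chunk <- 500
  for (s in seq(1, nrow(tv), by = chunk)) {
    e <- min(s + chunk - 1, nrow(tv))
    dd <- outer(rowSums(pts[s:e, , drop = FALSE]^2), rowSums(sv^2), "+") -
      2 * pts[s:e, , drop = FALSE] %*% t(sv)
    nn[s:e] <- max.col(-dd, ties.method = "first")
  }
  for (i in seq_len(nrow(tv))) {
    p <- pts[i, ]
    best <- NULL
    bestd <- Inf
    for (f in vf[[nn[i]]]) {
      tri <- faces[f, ]
      a <- sv[tri[1], ]; b <- sv[tri[2], ]; c <- sv[tri[3], ]
      # project p on triangle (clamped barycentric)
      ab <- b - a; ac <- c - a; ap <- p - a
      d00 <- sum(ab * ab); d01 <- sum(ab * ac); d11 <- sum(ac * ac)
      d20 <- sum(ap * ab); d21 <- sum(ap * ac)
      den <- d00 * d11 - d01 * d01
      if (abs(den) < 1e-12) next
      v <- (d11 * d20 - d01 * d21) / den
      w <- (d00 * d21 - d01 * d20) / den
      v <- min(max(v, 0), 1); w <- min(max(w, 0), 1)
      if (v + w > 1) { s2 <- v + w; v <- v / s2; w <- w / s2 }
      q <- a + v * ab + w * ac
      dist <- sqrt(sum((p - q)^2))
      if (dist < bestd) {
        bestd <- dist
        best <- list(tri = tri, bc = c(1 - v - w, v, w))
      }
    }
    if (is.null(best)) { qc[i] <- Inf; next }
    qc[i] <- bestd
    if (bestd <= max_dist)
      out[i, ] <- as.numeric(best$bc %*% vals[best$tri, , drop = FALSE])
  }
  res <- as_tibble(as.data.frame(out))
  names(res) <- colnames(vals)
  res$qc_dist <- qc
  res
}

#' Build a template from a cohort
#'
#' Default: the subject with the median periosteal volume (global size) is
#' designated as the template. With `refine_iter > 0`, an iterative
#' mean-shape refinement registers every subject to the current template,
#' averages the warped signed distance maps and re-extracts the mask (the
#' zero level of the mean), for a fixed number of iterations.
#'
#' @param masks list of periosteal masks (same grid).
#' @param spacing voxel spacing (mm).
#' @param refine_iter mean-shape refinement iterations (default 0);
#'   refinement alignment is affine-only.
#' @param ... unused (kept for extension).
#' @return a `template_space`: `mask`, `spacing`, `reference` (index of the
#'   designated subject), `refined`.
#' @export
build_template <- function(masks, spacing, refine_iter = 0, ...) {
  if (!length(masks)) stop("empty cohort")
  vols <- vapply(masks, sum, numeric(1))
  ref <- which.min(abs(vols - median(vols)))
  mask <- masks[[ref]]
  if (refine_iter > 0) {
    # affine-only alignment: averaging fully warped shapes would just
    # reproduce the current template, not the mean shape
    for (it in seq_len(refine_iter)) {
      acc <- array(0, dim(mask))
      for (m in masks) {
        tr <- register_to_template(m, mask, spacing, deformable = FALSE)
        sdf <- signed_distance(m, spacing)
        acc <- acc + resample_na0(sdf, tr)
      }
      mask <- acc / length(masks) <= 0
    }
  }
  structure(list(mask = mask, spacing = spacing, reference = ref,
                 refined = refine_iter > 0),
            class = "template_space")
}

resample_na0 <- function(map, transform) {
  out <- resample_to_template(map, transform)
  out[is.na(out)] <- max(map, na.rm = TRUE)
  out
}

#' Shape covariates from aligned periosteal meshes
#'
#' Generalized Procrustes alignment (translation and rotation only; scale is
#' retained, since bone size is biology) followed by PCA on the stacked
#' vertex coordinates. Returns the scores of the first `k` components,
#' where `k` defaults to the smaller of the component count reaching
#' `variance_target` and `k_max`.
#'
#' @param meshes list of `surface_mesh` objects with identical topology.
#' @param k_max maximum number of components (default 4).
#' @param variance_target cumulative variance target (default 0.9).
#' @param max_gpa_iter Procrustes iterations.
#' @return a `shape_covariates`: `scores` (n x k tibble, columns `shape_pc1`
#'   ...), `variance_explained`, `k`.
#' @export
shape_pca <- function(meshes, k_max = 4, variance_target = 0.9,
                      max_gpa_iter = 10) {
  n <- length(meshes)
  if (n < 2) stop("shape PCA needs at least two subjects")
  X <- lapply(meshes, function(m) m$vertices)
  nv <- nrow(X[[1]])
  if (any(vapply(X, nrow, integer(1)) != nv))
    stop("meshes must share topology")
  # centre
  X <- lapply(X, function(v) sweep(v, 2, colMeans(v)))
  ref <- X[[1]]
  for (it in seq_len(max_gpa_iter)) {
    X <- lapply(X, function(v) {
      s <- svd(t(v) %*% ref)
      R <- s$u %*% t(s$v)
      if (det(R) < 0) { s$u[, 3] <- -s$u[, 3]; R <- s$u %*% t(s$v) }
      v %*% R
    })
    new_ref <- Reduce(`+`, X) / n
    if (max(abs(new_ref - ref)) < 1e-10) break
    ref <- new_ref
  }
  M <- t(vapply(X, as.numeric, numeric(3 * nv)))
  pc <- prcomp(M, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k90 <- which(cumsum(ve) >= variance_target)[1]
  k <- min(max(k90, 1), k_max, n - 1)
  scores <- as_tibble(as.data.frame(pc$x[, seq_len(k), drop = FALSE]))
  names(scores) <- paste0("shape_pc", seq_len(k))
  structure(list(scores = scores, variance_explained = ve[seq_len(k)],
                 variance_all = ve, k = k, k_at_target = k90),
            class = "shape_covariates")
}
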