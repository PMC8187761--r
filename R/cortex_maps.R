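# Cortical surface mapping: Laplace potential across the cortex, periosteal
# surface mesh, streamline thickness, and streamline aggregates (SIT, mean
# BMD, mean SED).

#' Solve the Laplace equation across the cortical shell
#'
#' A harmonic potential on the cortical domain with Dirichlet bands just
#' outside the shell: 0 on the periosteal side, 1 on the endosteal side
#' (6-neighbour finite differences, SOR iteration). Axial end faces are
#' natural (no-flux) boundaries.
#'
#' @param seg a `compartment_segmentation` (uses `cortical_mask` and
#'   `periosteal_mask`).
#' @param band_width width (voxels) of the Dirichlet bands.
#' @param tol relative-change convergence tolerance.
#' @param max_iter iteration cap.
#' @return list: `potential` (array, `NA` outside domain+bands), `domain`,
#'   `converged`, `iterations`.
#' @export
solve_laplace_cortex <- function(seg, band_width = 2.2, tol = 1e-6,
                                 max_iter = 5000) {
  d <- dim(seg$cortical_mask)
  domain <- seg$cortical_mask
  if (!any(domain)) stop("empty cortical domain")
  shellnb <- dilate_mask(domain, band_width) & !domain
  band0 <- shellnb & !seg$periosteal_mask        # periosteal (outer) side
  band1 <- shellnb & seg$periosteal_mask         # endosteal (inner) side
  if (!any(band0) || !any(band1))
    stop("cortical domain does not separate periosteal and endosteal sides")
  sol <- cpp_laplace(as.logical(domain), as.logical(band0),
                     as.logical(band1), d, tol, max_iter)
  list(potential = array(sol$potential, d), domain = domain,
       band0 = band0, band1 = band1,
       converged = sol$converged, iterations = sol$iterations)
}

#' Extract a periosteal surface mesh by radial sampling
#'
#' The distal radius is tubular, so the periosteal surface is parameterized
#' cylindrically: on each slice the mask contour is sampled at `n_angles`
#' equally spaced rays from the slice centroid (sub-voxel radius from the
#' 0.5 level of the lightly smoothed mask), and consecutive slice rings are
#' stitched into a closed triangle strip. All subjects share the
#' (slice, angle) grid topology, which the template correspondence relies
#' on.
#'
#' @param periosteal_mask logical array with spacing attribute (or pass
#'   `spacing`).
#' @param n_angles vertices per slice ring.
#' @param spacing voxel spacing (mm).
#' @param slice_range slices to mesh (default trims one end slice each side).
#' @return a `surface_mesh` list: `vertices` (V x 3 mm), `faces` (F x 3,
#'   1-based), `n_angles`, `slices`.
#' @export
periosteal_mesh <- function(periosteal_mask, n_angles = 48, spacing = NULL,
                            slice_range = NULL) {
  if (is.null(spacing)) spacing <- attr(periosteal_mask, "spacing")
  stopifnot(!is.null(spacing))
  d <- dim(periosteal_mask)
  if (is.null(slice_range)) slice_range <- c(2L, d[3] - 1L)
  slices <- seq(slice_range[1], slice_range[2])
  theta <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  verts <- matrix(NA_real_, length(slices) * n_angles, 3)
  # smooth each slice and sample radii along rays by bisecting the 0.5 level
  for (si in seq_along(slices)) {
    z <- slices[si]
    sl <- array(as.numeric(periosteal_mask[, , z]), c(d[1], d[2], 1))
    k <- gaussian_kernel3(spacing[1], c(spacing[1], spacing[2],
                                        max(spacing)))
    k <- k[, , (dim(k)[3] + 1) / 2, drop = FALSE]
    k <- k / sum(k)
    sm <- fft_convolve3(sl, k)[, , 1, drop = TRUE]
    idx <- which(periosteal_mask[, , z], arr.ind = TRUE)
    if (!nrow(idx)) stop(sprintf("slice %d has no periosteal voxels", z))
    cx <- mean((idx[, 1] - 1) * spacing[1])
    cy <- mean((idx[, 2] - 1) * spacing[2])
    rmax <- max(sqrt(((idx[, 1] - 1) * spacing[1] - cx)^2 +
                     ((idx[, 2] - 1) * spacing[2] - cy)^2)) + 2 * spacing[1]
    interp2 <- function(px, py) {
      co <- cbind(px / spacing[1], py / spacing[2], 0)
      cpp_trilinear(as.numeric(sm), c(d[1], d[2], 1L), co, 0)
    }
    ct <- cos(theta); st <- sin(theta)
    lo <- rep(0, n_angles)
    hi <- rep(rmax, n_angles)
    # bisect the 0.5 level along all rays simultaneously
    for (it in 1:36) {
      mid <- (lo + hi) / 2
      inside <- interp2(cx + mid * ct, cy + mid * st) >= 0.5
      lo[inside] <- mid[inside]
      hi[!inside] <- mid[!inside]
    }
    r <- (lo + hi) / 2
    verts[(si - 1) * n_angles + seq_len(n_angles), ] <-
      cbind(cx + r * ct, cy + r * st, (z - 1) * spacing[3])
  }
  faces <- NULL
  nr <- length(slices)
  fa <- vector("list", (nr - 1))
  for (si in seq_len(nr - 1)) {
    a <- (si - 1) * n_angles + seq_len(n_angles)
    b <- si * n_angles + seq_len(n_angles)
    an <- c(a[-1], a[1])
    bn <- c(b[-1], b[1])
    fa[[si]] <- rbind(cbind(a, b, an), cbind(b, bn, an))
  }
  faces <- do.call(rbind, fa)
  structure(list(vertices = verts, faces = faces, n_angles = n_angles,
                 slices = slices, spacing = spacing),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices (%d rings x %d), %d faces\n",
              nrow(x$vertices), length(x$slices), x$n_angles,
              nrow(x$faces)))
  invisible(x)
}

#' Trace cortical streamlines from periosteal seeds
#'
#' Integrates the normalized gradient of the Laplace potential from each
#' mesh vertex to the endosteal side; the arc length is the apparent
#' cortical thickness at that vertex. The trace is terminated at the
#' sub-voxel 0.5 level of the lightly smoothed cortical mask (the endosteal
#' surface itself), which avoids the half-voxel offset of the Dirichlet
#' bands.
#'
#' @param laplace result of [solve_laplace_cortex()].
#' @param mesh a `surface_mesh` whose vertices seed the streamlines.
#' @param spacing voxel spacing (mm).
#' @param step integration step in mm (default half a voxel).
#' @param max_len trajectory cap in mm.
#' @return a `streamline_set` list: `arc_length` (mm per vertex, `NA` where
#'   flagged), `ok` flags, `points` (list of polylines, mm).
#' @export
trace_streamlines <- function(laplace, mesh, spacing, step = NULL,
                              max_len = NULL) {
  if (is.null(step)) step <- min(spacing) / 2
  if (is.null(max_len))
    max_len <- sum(dim(laplace$potential) * spacing)
  ind <- gaussian_blur(bone_volume(
    array(as.numeric(laplace$domain), dim(laplace$domain)), spacing),
    min(spacing))
  tr <- cpp_trace_streamlines(as.numeric(laplace$potential),
                              dim(laplace$potential), spacing,
                              as.matrix(mesh$vertices), step, max_len,
                              phi_stop = 0.999,
                              indicator = as.numeric(vol_array(ind)))
  arc <- tr$arc_length
  arc[!tr$ok] <- NA_real_
  structure(list(arc_length = arc, ok = tr$ok, points = tr$points,
                 step = step),
            class = "streamline_set")
}

#' Aggregate maps along streamlines
#'
#' Composite-trapezoid integrals along each streamline: the streamline
#' integral thickness (SIT) is the integral of the soft cortical membership;
#' BMD and SED are arc-length-weighted means. Flagged vertices propagate as
#' `NA`.
#'
#' @param streamlines a `streamline_set`.
#' @param membership soft cortical membership array in `[0, 1]`.
#' @param bmd BMD array (mg/cm^3); `sed` optional SED array.
#' @param sed optional SED array (J/mm^3).
#' @param spacing voxel spacing (mm).
#' @return tibble with one row per seed vertex: `surf_app_ct_th`,
#'   `surf_ct_sit`, `surf_ct_bmd`, and `surf_ct_sed` when `sed` is given.
#' @export
surface_aggregates <- function(streamlines, membership, bmd, sed = NULL,
                               spacing) {
  ns <- length(streamlines$points)
  npts_all <- vapply(streamlines$points, function(p)
    if (is.matrix(p)) nrow(p) else 0L, integer(1))
  usable <- which(streamlines$ok & npts_all >= 2)
  out <- matrix(NA_real_, ns, 3 + !is.null(sed))
  colnames(out) <- c("surf_app_ct_th", "surf_ct_sit", "surf_ct_bmd",
                     if (!is.null(sed)) "surf_ct_sed")
  if (length(usable)) {
    npts <- vapply(streamlines$points[usable], nrow, integer(1))
    all_pts <- do.call(rbind, streamlines$points[usable])
    id <- rep(seq_along(usable), npts)
    # trapezoid weights per polyline
    seglen <- sqrt(rowSums((all_pts[-1, , drop = FALSE] -
                            all_pts[-nrow(all_pts), , drop = FALSE])^2))
    last <- cumsum(npts)
    first <- c(1, last[-length(last)] + 1)
    seglen[last[-length(last)]] <- 0 # sever spurious cross-polyline segments
    w <- c(seglen / 2, 0) + c(0, seglen / 2)
    L <- vapply(seq_along(usable), function(i)
      sum(seglen[first[i]:max(first[i], last[i] - 1)]), numeric(1))
    sum_by <- function(x) as.numeric(rowsum(x, id))
    mvals <- sample_trilinear(membership, all_pts, spacing, fill = 0)
    bvals <- sample_trilinear(bmd, all_pts, spacing, fill = NA_real_)
    bna <- is.na(bvals)
    out[usable, "surf_app_ct_th"] <- streamlines$arc_length[usable]
    out[usable, "surf_ct_sit"] <- sum_by(w * mvals)
    den <- sum_by(w * !bna)
    num <- sum_by(w * ifelse(bna, 0, bvals))
    out[usable, "surf_ct_bmd"] <- ifelse(den > 0, num / den, NA_real_)
    if (!is.null(sed)) {
      svals <- sample_trilinear(sed, all_pts, spacing, fill = 0)
      out[usable, "surf_ct_sed"] <- ifelse(L > 0, sum_by(w * svals) / L,
                                           NA_real_)
    }
  }
  as_tibble(as.data.frame(out))
}

#' Cortical surface map set for one subject
#'
#' Runs the full cortical pipeline: Laplace potential, periosteal mesh,
#' streamlines, and the per-vertex aggregates.
#'
#' @param vol a [bone_volume()]; `seg` its segmentation.
#' @param seg a `compartment_segmentation`.
#' @param sed_map optional SED array from [fe_sed_map()].
#' @param n_angles mesh vertices per slice ring.
#' @param ... passed to [solve_laplace_cortex()].
#' @return a `surface_map_set`: `mesh`, per-vertex tibble `values`
#'   (`surf_app_ct_th`, `surf_ct_sit`, `surf_ct_bmd`, `surf_ct_sed`),
#'   `streamlines`, `laplace_converged`.
#' @export
surface_map_set <- function(vol, seg, sed_map = NULL, n_angles = 48, ...) {
  sp <- vol_spacing(vol)
  lap <- solve_laplace_cortex(seg, ...)
  mesh <- periosteal_mesh(seg$periosteal_mask, n_angles, spacing = sp)
  str <- trace_streamlines(lap, mesh, sp)
  vals <- surface_aggregates(str, seg$membership, vol_array(vol),
                             sed = sed_map, spacing = sp)
  structure(list(mesh = mesh, values = vals, streamlines = str,
                 laplace_converged = lap$converged),
            class = "surface_map_set")
}

#' Write a mesh with per-vertex scalars as PLY
#'
#' Binary little-endian PLY with float vertex properties named after the
#' columns of `values`.
#'
#' @param mesh a `surface_mesh`.
#' @param values data frame of per-vertex scalars (may be `NULL`).
#' @param path output path.
#' @param ascii write ASCII PLY instead of binary little-endian.
#' @return `path`, invisibly.
#' @export
write_surface_ply <- function(mesh, values = NULL, path, ascii = FALSE) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  props <- if (is.null(values)) character(0) else colnames(values)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (ascii) "ascii" else "binary_little_endian"),
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           sprintf("property float %s", props),
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  vdata <- cbind(mesh$vertices,
                 if (!is.null(values)) as.matrix(values) else NULL)
  vdata[is.na(vdata)] <- NaN
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  f0 <- mesh$faces - 1L # 0-based
  if (ascii) {
    writeLines(apply(vdata, 1, function(r)
      paste(formatC(r, format = "g", digits = 7), collapse = " ")), con)
    writeLines(apply(f0, 1, function(r)
      paste(c(3L, r), collapse = " ")), con)
  } else {
    writeBin(as.numeric(t(vdata)), con, size = 4, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[i, ]), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}
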