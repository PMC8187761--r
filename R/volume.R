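#' Calibrated 3D bone volume
#'
#' A `bone_volume` is a 3D numeric array of volumetric bone mineral density
#' (mg HA/cm^3) with isotropic-or-not voxel spacing in mm attached. Axis 3 is
#' the bone axis; slice 1 is the distal end. Voxel indices are 1-based in R;
#' the world coordinate of voxel centre `(i, j, k)` is
#' `((i-1)*sx, (j-1)*sy, (k-1)*sz)` mm.
#'
#' @param data 3D numeric array of BMD values (mg/cm^3).
#' @param spacing numeric length-1 or length-3 voxel spacing in mm.
#' @return An object of class `bone_volume`.
#' @export
bone_volume <- function(data, spacing = 0.082) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  structure(data, spacing = as.numeric(spacing), class = "bone_volume")
}

#' @export
print.bone_volume <- function(x, ...) {
  d <- dim(x)
  sp <- vol_spacing(x)
  cat(sprintf("<bone_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  cat(sprintf("  BMD range: %.1f .. %.1f mg/cm^3\n",
              min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  invisible(x)
}

#' Voxel spacing of a volume or mask
#' @param x a `bone_volume` or any array carrying a `spacing` attribute.
#' @return numeric length-3 spacing in mm.
#' @export
vol_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) stop("object carries no voxel spacing")
  sp
}

vol_array <- function(x) {
  a <- unclass(x)
  attr(a, "spacing") <- NULL
  a
}

same_grid <- function(a, b) identical(dim(a), dim(b))

#' Read / write calibrated volumes as NIfTI
#'
#' Spacing is carried in the NIfTI `pixdim` field. Values are stored as-is
#' (mg/cm^3).
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a [bone_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  bone_volume(array(as.numeric(img), dim = dim(img)),
              spacing = RNifti::pixdim(img)[seq_len(3)])
}

#' @param vol a [bone_volume()].
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol_array(vol), reference = NULL)
  RNifti::pixdim(img) <- vol_spacing(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- array utilities ------------------------------------------------------

#' Otsu threshold of a numeric vector
#'
#' Maximises between-class variance on a 256-bin histogram and returns the
#' midpoint of the two class means at the optimal split (well-defined even
#' for spiky histograms where any value between the modes classifies
#' identically). Used as the self-calibrating default for periosteal and
#' bone thresholds.
#' @param x numeric values.
#' @param n_bins histogram bins.
#' @return threshold on the scale of `x`.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- as.numeric(tabulate(findInterval(x, br, all.inside = TRUE),
                           nbins = n_bins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot_w <- w[n_bins]
  tot_mu <- mu[n_bins]
  w1 <- w
  w2 <- tot_w - w
  valid <- w1 > 0 & w2 > 0
  m1 <- mu / w1
  m2 <- (tot_mu - mu) / w2
  bc <- ifelse(valid, w1 * w2 * (m1 - m2)^2, -Inf)
  i <- which.max(bc)
  (m1[i] + m2[i]) / 2
}

# full 3D convolution by FFT, returning the "same"-size central part.
# kernel dims must be odd.
fft_convolve3 <- function(x, kernel) {
  dx <- dim(x)
  dk <- dim(kernel)
  stopifnot(all(dk %% 2 == 1))
  dp <- dx + dk - 1
  xp <- array(0, dp)
  xp[seq_len(dx[1]), seq_len(dx[2]), seq_len(dx[3])] <- x
  kp <- array(0, dp)
  kp[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kernel
  conv <- Re(fft(fft(xp) * fft(kp), inverse = TRUE)) / prod(dp)
  off <- (dk - 1) / 2
  conv[off[1] + seq_len(dx[1]), off[2] + seq_len(dx[2]),
       off[3] + seq_len(dx[3]), drop = FALSE]
}

# binary spherical structuring element of radius r (voxel units, anisotropy
# via spacing); includes voxels whose centre distance <= r.
sphere_kernel <- function(r_voxels, spacing = c(1, 1, 1)) {
  rv <- ceiling(r_voxels / (spacing / min(spacing)))
  ax <- lapply(rv, function(m) seq(-m, m))
  g <- expand.grid(x = ax[[1]] * spacing[1] / min(spacing),
                   y = ax[[2]] * spacing[2] / min(spacing),
                   z = ax[[3]] * spacing[3] / min(spacing))
  k <- array(as.numeric(sqrt(g$x^2 + g$y^2 + g$z^2) <= r_voxels + 1e-9),
             dim = 2 * rv + 1)
  k
}

# isotropic Gaussian kernel in mm, truncated at 3 sigma
gaussian_kernel3 <- function(sigma_mm, spacing) {
  rv <- pmax(1L, ceiling(3 * sigma_mm / spacing))
  ax <- lapply(seq_len(3), function(d) (-rv[d]:rv[d]) * spacing[d])
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  k <- exp(-(g$x^2 + g$y^2 + g$z^2) / (2 * sigma_mm^2))
  array(k / sum(k), dim = 2 * rv + 1)
}

#' Gaussian blur of a volume
#' @param vol a [bone_volume()] or 3D array.
#' @param sigma_mm isotropic standard deviation in mm; 0 returns the input.
#' @return blurred object of the same class.
#' @export
gaussian_blur <- function(vol, sigma_mm) {
  if (sigma_mm <= 0) return(vol)
  sp <- if (inherits(vol, "bone_volume")) vol_spacing(vol) else c(1, 1, 1)
  k <- gaussian_kernel3(sigma_mm, sp)
  out <- fft_convolve3(if (inherits(vol, "bone_volume")) vol_array(vol) else vol, k)
  if (inherits(vol, "bone_volume")) bone_volume(out, sp) else out
}

# mean filter over an isotropic spherical kernel (radius in voxels)
# restricted to a domain; NA where the kernel meets no domain voxel.
sphere_mean <- function(x, domain, radius_voxels) {
  k <- sphere_kernel(radius_voxels)
  xd <- x
  xd[!domain] <- 0
  num <- fft_convolve3(xd, k)
  den <- fft_convolve3(array(as.numeric(domain), dim(x)), k)
  out <- num / den
  out[den < 0.5] <- NA_real_
  out
}

# cube-kernel box mean / morphology via shifted adds: much cheaper than the
# EDT or FFT routes for the small radii used inside the segmentation
box_mean <- function(x, domain, r) {
  xd <- x
  xd[!domain] <- 0
  num <- box3_sum(xd, r)
  den <- box3_sum(array(as.numeric(domain), dim(x)), r)
  out <- num / den
  out[den < 0.5] <- NA_real_
  out
}

box_dilate <- function(mask, r = 1) {
  box3_sum(array(as.numeric(mask), dim(mask)), r) > 0.5
}

box_erode <- function(mask, r = 1) {
  !box_dilate(!mask, r)
}

box_close <- function(mask, r = 1) {
  box_erode(box_dilate(mask, r), r)
}

# logical erosion/dilation with a spherical element via the EDT
erode_mask <- function(mask, r_voxels, spacing = c(1, 1, 1)) {
  d <- cpp_edt3d(as.logical(mask), dim(mask), spacing / min(spacing))
  out <- array(d > r_voxels + 1e-9, dim(mask))
  out
}

dilate_mask <- function(mask, r_voxels, spacing = c(1, 1, 1)) {
  !erode_mask(!mask, r_voxels, spacing)
}

close_mask <- function(mask, r_voxels, spacing = c(1, 1, 1)) {
  if (r_voxels <= 0) return(mask)
  erode_mask(dilate_mask(mask, r_voxels, spacing), r_voxels, spacing)
}

largest_component <- function(mask, connectivity = 6) {
  lab <- cpp_label3d(as.logical(mask), dim(mask), connectivity)
  n <- attr(lab, "n_components")
  if (n == 0) return(array(FALSE, dim(mask)))
  tab <- tabulate(lab[lab > 0], nbins = n)
  array(lab == which.max(tab), dim(mask))
}

# distance (mm) to the periosteal surface for voxels inside the mask
periosteal_distance_map <- function(periosteal_mask, spacing) {
  d <- cpp_edt3d(as.logical(periosteal_mask), dim(periosteal_mask), spacing)
  array(d, dim(periosteal_mask))
}

#' Trilinear interpolation of a volume at world coordinates
#' @param arr 3D array (or `bone_volume`).
#' @param coords_mm n x 3 matrix of world coordinates (mm).
#' @param spacing voxel spacing, taken from `arr` when it is a `bone_volume`.
#' @param fill value for out-of-grid samples.
#' @return numeric vector of interpolated values.
#' @export
sample_trilinear <- function(arr, coords_mm, spacing = NULL, fill = NA_real_) {
  if (inherits(arr, "bone_volume")) {
    spacing <- vol_spacing(arr)
    arr <- vol_array(arr)
  }
  stopifnot(!is.null(spacing))
  vox <- sweep(coords_mm, 2, spacing, "/")
  cpp_trilinear(as.numeric(arr), dim(arr), as.matrix(vox), fill)
}
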