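# 24 x 24 stiffness matrix of an 8-node trilinear hexahedral element with
# edge lengths h = (hx, hy, hz), isotropic linear elastic material (E in MPa,
# so with mm lengths forces come out in N and energies in N*mm = mJ).
# Local node order: corner (a, b, c) -> node index 1 + a + 2b + 4c.
hex8_stiffness <- function(E, nu, h) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  signs <- as.matrix(expand.grid(a = c(-1, 1), b = c(-1, 1), c = c(-1, 1)))
  gp <- c(-1, 1) / sqrt(3)
  ke <- matrix(0, 24, 24)
  detJ <- prod(h) / 8
  for (gx in gp) for (gy in gp) for (gz in gp) {
    B <- matrix(0, 6, 24)
    for (n in 1:8) {
      s <- signs[n, ]
      dN <- c(s[1] * (1 + s[2] * gy) * (1 + s[3] * gz) / 8 * 2 / h[1],
              s[2] * (1 + s[1] * gx) * (1 + s[3] * gz) / 8 * 2 / h[2],
              s[3] * (1 + s[1] * gx) * (1 + s[2] * gy) / 8 * 2 / h[3])
      col <- 3 * (n - 1)
      B[1, col + 1] <- dN[1]
      B[2, col + 2] <- dN[2]
      B[3, col + 3] <- dN[3]
      B[4, col + 1] <- dN[2]; B[4, col + 2] <- dN[1]
      B[5, col + 2] <- dN[3]; B[5, col + 3] <- dN[2]
      B[6, col + 1] <- dN[3]; B[6, col + 3] <- dN[1]
    }
    ke <- ke + t(B) %*% D %*% B * detJ
  }
  (ke + t(ke)) / 2
}

#' Build a voxel micro-FE model from a segmentation
#'
#' One 8-node hexahedral element per bone voxel. Elements whose
#' face-connected component does not reach both axial end faces of the
#' element set carry no load and are removed (their count is reported).
#'
#' @param seg a `compartment_segmentation`, or a list with `bone_mask`.
#' @param spacing voxel spacing in mm (taken from `seg$spacing` if present).
#' @param elastic_modulus tissue modulus in MPa (default 6829, i.e.
#'   6.829 GPa).
#' @param poisson_ratio Poisson ratio (default 0.3).
#' @param applied_strain axial compressive strain (default 0.01 = 1 %).
#' @param lateral `"free"` (end faces constrained axially only) or
#'   `"pinned"` (end-face nodes fully fixed / fully prescribed).
#' @return an `fe_model` list: element voxel indices, compact node numbering,
#'   element-node incidence, constants, removal count.
#' @export
build_fe_model <- function(seg, spacing = NULL, elastic_modulus = 6829,
                           poisson_ratio = 0.3, applied_strain = 0.01,
                           lateral = c("free", "pinned")) {
  lateral <- match.arg(lateral)
  mask <- if (is.list(seg)) seg$bone_mask else seg
  if (is.null(spacing)) spacing <- seg$spacing
  stopifnot(!is.null(spacing))
  if (!any(mask)) stop("bone mask is empty")
  d <- dim(mask)
  zidx <- which(apply(mask, 3, any))
  zmin <- min(zidx); zmax <- max(zidx)
  lab <- array(cpp_label3d(as.logical(mask), d, 6), d)
  keep_labels <- intersect(unique(lab[, , zmin][mask[, , zmin]]),
                           unique(lab[, , zmax][mask[, , zmax]]))
  keep_labels <- keep_labels[keep_labels > 0]
  if (!length(keep_labels))
    stop("no axially spanning bone component: model is unsolvable")
  keep <- array(lab %in% keep_labels, d) & mask
  n_removed <- sum(mask) - sum(keep)
  el <- which(keep, arr.ind = TRUE) # (i, j, k), 1-based voxel indices
  el <- el[order(el[, 3], el[, 2], el[, 1]), , drop = FALSE]
  nn_grid <- d + 1L
  corner_id <- function(i, j, k) i + nn_grid[1] * ((j - 1) + nn_grid[2] * (k - 1))
  # local corner offsets in node order 1 + a + 2b + 4c
  offs <- as.matrix(expand.grid(a = 0:1, b = 0:1, c = 0:1))
  enodes_raw <- matrix(0L, nrow(el), 8)
  for (n in 1:8)
    enodes_raw[, n] <- corner_id(el[, 1] + offs[n, 1], el[, 2] + offs[n, 2],
                                 el[, 3] + offs[n, 3])
  node_ids <- sort(unique(as.integer(enodes_raw)))
  enodes <- matrix(match(enodes_raw, node_ids), nrow(el), 8)
  # node grid coordinates (0-based corner indices)
  k0 <- (node_ids - 1) %/% (nn_grid[1] * nn_grid[2])
  rem <- (node_ids - 1) %% (nn_grid[1] * nn_grid[2])
  j0 <- rem %/% nn_grid[1]
  i0 <- rem %% nn_grid[1]
  structure(list(
    dim = d, spacing = spacing, elements = el, element_nodes = enodes,
    node_grid = cbind(i = i0, j = j0, k = k0), n_nodes = length(node_ids),
    zmin = zmin, zmax = zmax,
    elastic_modulus = elastic_modulus, poisson_ratio = poisson_ratio,
    applied_strain = applied_strain, lateral = lateral,
    n_removed = n_removed), class = "fe_model")
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("<fe_model> %d elements, %d nodes (%d floating removed)\n",
              nrow(x$elements), x$n_nodes, x$n_removed))
  cat(sprintf("  E = %g MPa, nu = %g, applied strain = %g, lateral %s\n",
              x$elastic_modulus, x$poisson_ratio, x$applied_strain, x$lateral))
  invisible(x)
}

assemble_stiffness <- function(model) {
  ke <- hex8_stiffness(model$elastic_modulus, model$poisson_ratio,
                       model$spacing)
  en <- model$element_nodes
  nel <- nrow(en)
  ndof <- 3L * model$n_nodes
  # global dof of local (node n, component c): 3*(en[,n]-1)+c
  ii <- integer(576L * nel)
  jj <- integer(576L * nel)
  xx <- numeric(576L * nel)
  pos <- 0L
  for (na in 1:8) for (ca in 1:3) {
    ga <- 3L * (en[, na] - 1L) + ca
    ra <- 3L * (na - 1L) + ca
    for (nb in 1:8) for (cb in 1:3) {
      rb <- 3L * (nb - 1L) + cb
      v <- ke[ra, rb]
      idx <- pos + seq_len(nel)
      ii[idx] <- ga
      jj[idx] <- 3L * (en[, nb] - 1L) + cb
      xx[idx] <- v
      pos <- pos + nel
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
}

# preconditioned conjugate gradients with Jacobi preconditioner
pcg_solve <- function(A, b, tol = 1e-6, max_iter = 1000) {
  dA <- Matrix::diag(A)
  dA[dA <= 0] <- 1
  x <- numeric(length(b))
  r <- b
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(list(x = x, iterations = 0, residual = 0,
                           converged = TRUE))
  z <- r / dA
  p <- z
  rz <- sum(r * z)
  it <- 0
  repeat {
    it <- it + 1
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / nb
    if (res < tol || it >= max_iter) break
    z <- r / dA
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, iterations = it, residual = res, converged = res < tol)
}

#' Solve the axial compression problem
#'
#' Boundary conditions: distal-face nodes are fixed axially, proximal-face
#' nodes are displaced axially by `applied_strain` times the axial length;
#' lateral components are free unless the model was built with
#' `lateral = "pinned"`. The linear elastic system is solved by Jacobi-
#' preconditioned conjugate gradients to a relative residual below `tol`.
#'
#' @param model an [build_fe_model()] result.
#' @param tol relative residual tolerance.
#' @param max_iter iteration cap; default `ceiling(10 * sqrt(n_nodes))` but
#'   at least 500.
#' @return an `fe_result` list: full displacement vector (mm, 3 dofs/node),
#'   `reaction_force` (N), `stiffness` (N/mm), per-element `sed` (J/mm^3),
#'   energy-balance ratio, solver iterations and residual.
#' @export
solve_compression <- function(model, tol = 1e-6, max_iter = NULL) {
  if (is.null(max_iter))
    max_iter <- max(500L, ceiling(10 * sqrt(model$n_nodes)))
  K <- assemble_stiffness(model)
  ndof <- 3L * model$n_nodes
  kz <- model$node_grid[, "k"]
  bottom <- kz == (model$zmin - 1L)      # corner layer at distal face
  top <- kz == model$zmax                # corner layer at proximal face
  L <- (model$zmax - model$zmin + 1L) * model$spacing[3]
  delta <- model$applied_strain * L
  u <- numeric(ndof)
  fixed <- logical(ndof)
  zdof <- function(sel) 3L * (which(sel) - 1L) + 3L
  fixed[zdof(bottom)] <- TRUE
  fixed[zdof(top)] <- TRUE
  u[zdof(top)] <- -delta
  if (model$lateral == "pinned") {
    for (cmp in 1:2) {
      fixed[3L * (which(bottom | top) - 1L) + cmp] <- TRUE
    }
  }
  free <- !fixed
  if (model$applied_strain == 0) {
    sol <- list(x = numeric(sum(free)), iterations = 0, residual = 0,
                converged = TRUE)
  } else {
    b <- -as.numeric(K[free, fixed, drop = FALSE] %*% u[fixed])
    sol <- pcg_solve(K[free, free], b, tol, max_iter)
    if (!sol$converged)
      stop(sprintf(paste0("micro-FE solver did not converge: residual %.3g ",
                          "after %d iterations"), sol$residual,
                   sol$iterations))
  }
  u[free] <- sol$x
  reac <- as.numeric(K %*% u)
  f_top <- sum(reac[zdof(top)])
  f_bottom <- sum(reac[zdof(bottom)])
  reaction_force <- abs(f_top)
  stiffness <- if (delta > 0) reaction_force / delta else 0
  # per-element strain energy density
  ke <- hex8_stiffness(model$elastic_modulus, model$poisson_ratio,
                       model$spacing)
  en <- model$element_nodes
  U <- matrix(0, nrow(en), 24)
  for (n in 1:8) for (cmp in 1:3)
    U[, 3 * (n - 1) + cmp] <- u[3L * (en[, n] - 1L) + cmp]
  volel <- prod(model$spacing)
  # with E in MPa and lengths in mm, element energies are N*mm and the
  # density below is numerically 0.5*E*eps^2 (= 0.34145 for E = 6829 MPa at
  # 1 % strain), the scale on which SED is conventionally reported
  sed <- rowSums((U %*% ke) * U) / 2 / volel
  structure(list(
    displacements = u, reaction_force = reaction_force,
    stiffness = stiffness, sed = pmax(sed, 0),
    force_balance = abs(f_top + f_bottom) /
      max(abs(f_top), .Machine$double.eps),
    energy_balance = if (delta > 0)
      sum(sed) * volel / (0.5 * reaction_force * delta) else 1,
    applied_displacement = delta,
    solver_iters = sol$iterations, residual = sol$residual),
    class = "fe_result")
}

#' @export
print.fe_result <- function(x, ...) {
  cat(sprintf("<fe_result> F = %.4g N, stiffness = %.4g N/mm\n",
              x$reaction_force, x$stiffness))
  cat(sprintf("  SED mean %.4g, max %.4g J/mm^3; %d CG iters, residual %.2g\n",
              mean(x$sed), max(x$sed), x$solver_iters, x$residual))
  invisible(x)
}

#' Estimate failure load from the linear solution
#'
#' Critical-strain criterion: the effective strain of each element is the
#' energy-equivalent `sqrt(2 * SED / E)`; the linear solution is scaled so
#' that `critical_volume_fraction` of the tissue volume exceeds
#' `critical_strain`, and the failure load is the scaled reaction force.
#' Defaults 0.7 % critical strain in 2 % of the tissue.
#'
#' @param result an `fe_result`; `model` the matching `fe_model`.
#' @param model the `fe_model` the result was computed from.
#' @param critical_strain effective-strain threshold (default 0.007).
#' @param critical_volume_fraction tissue volume fraction (default 0.02).
#' @return failure load in N.
#' @export
failure_load <- function(result, model, critical_strain = 0.007,
                         critical_volume_fraction = 0.02) {
  if (!length(result$sed)) stop("empty element set")
  eff <- sqrt(2 * result$sed / model$elastic_modulus)
  if (all(eff <= 0)) return(0)
  # strain exceeded by exactly critical_volume_fraction of element volume
  # (equal-volume elements: upper quantile of the effective strains)
  q <- quantile(eff, probs = 1 - critical_volume_fraction, type = 1,
                names = FALSE)
  s <- critical_strain / q
  result$reaction_force * s
}
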