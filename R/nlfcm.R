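# Non-local fuzzy c-means for the endosteal boundary.
#
# Clustering features are the BMD map, the binary bone segmentation and the
# distance to the periosteal surface, z-scored over the periosteal interior.
# The spatial regularization follows the FCM_S family: alongside each voxel's
# own feature vector, the weighted average feature vector of its K most
# similar patches inside a search window enters the objective,
#
#   J(U, V) = sum_ic u_ic^m ( ||x_i - v_c||^2 + lambda ||xbar_i - v_c||^2 ),
#
# which alternating membership/centroid updates minimize, so J is
# non-increasing by construction. lambda = 0 recovers plain FCM.

# box-filter sum over a cube of half-width r (zero padding at the borders)
box3_sum <- function(a, r) {
  array(cpp_box3_sum(as.numeric(a), dim(a), as.integer(r)), dim(a))
}

shift_array <- function(a, o, fill = NA_real_) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (o[k] >= 0) {
      src[[k]] <- seq_len(d[k] - o[k]) + o[k]
      dst[[k]] <- seq_len(d[k] - o[k])
    } else {
      src[[k]] <- seq_len(d[k] + o[k])
      dst[[k]] <- seq_len(d[k] + o[k]) - o[k]
    }
    if (length(src[[k]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Non-local average of feature arrays: for each voxel, average the feature
# vectors found at the centres of its K most similar patches (patch
# half-width patch_r) within the search window (half-width window_r),
# excluding the zero offset.
nl_average_features <- function(feats, window_r = 3, patch_r = 1, K = 6) {
  d <- dim(feats[[1]])
  n <- prod(d)
  offs <- expand.grid(x = -window_r:window_r, y = -window_r:window_r,
                      z = -window_r:window_r)
  offs <- offs[!(offs$x == 0 & offs$y == 0 & offs$z == 0), ]
  nf <- length(feats)
  Dk <- matrix(Inf, n, K)          # K smallest patch distances so far
  Sk <- array(0, c(n, K, nf))      # matching shifted feature vectors
  for (r in seq_len(nrow(offs))) {
    o <- as.integer(offs[r, ])
    dist2 <- array(0, d)
    sh <- vector("list", nf)
    bad <- array(FALSE, d)
    for (f in seq_len(nf)) {
      s <- shift_array(feats[[f]], o)
      bad <- bad | is.na(s)
      s[is.na(s)] <- 0
      sh[[f]] <- s
      dist2 <- dist2 + (feats[[f]] - s)^2
    }
    Do <- as.numeric(box3_sum(dist2, patch_r))
    Do[as.logical(bad)] <- Inf
    worst_col <- max.col(Dk, ties.method = "first")
    worst <- Dk[cbind(seq_len(n), worst_col)]
    better <- which(Do < worst)
    if (length(better)) {
      put <- cbind(better, worst_col[better])
      Dk[put] <- Do[better]
      for (f in seq_len(nf))
        Sk[cbind(put, f)] <- sh[[f]][better]
    }
  }
  valid <- is.finite(Dk)
  cnt <- rowSums(valid)
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    s <- rowSums(Sk[, , f] * valid)
    m <- ifelse(cnt > 0, s / cnt, 0)
    out[[f]] <- array(m, d)
  }
  attr(out, "n_neighbors") <- cnt
  out
}

#' Refine the endosteal boundary with non-local fuzzy c-means
#'
#' Clusters periosteal-interior voxels into cortical-like and trabecular-like
#' classes using BMD, the binary bone segmentation and the distance to the
#' periosteal surface as features (z-scored per subject). A non-local term
#' (weight `lambda`) couples each voxel to the average features of its `K`
#' most similar patches in a search window, which regularizes the memberships
#' spatially. Cluster identity is resolved by mean periosteal distance
#' (cortical = smaller).
#'
#' @param vol a [bone_volume()].
#' @param bone_mask,periosteal_mask,periosteal_distance from the compartment
#'   segmentation.
#' @param fuzzifier FCM fuzzifier m (> 1, default 2).
#' @param lambda non-local regularization weight (0 disables the term).
#' @param window_r,patch_r,K search-window and patch half-widths (voxels) and
#'   neighbour count of the non-local term.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap; non-convergence returns the last iterate
#'   with `converged = FALSE`.
#' @return list: `cortical_mask`, `trabecular_mask` (hard labels by maximum
#'   membership), `membership_cortical` array, `objective` trace, `converged`,
#'   `degenerate` flags.
#' @export
nlfcm_endosteal <- function(vol, bone_mask, periosteal_mask,
                            periosteal_distance,
                            fuzzifier = 2, lambda = 0.5,
                            window_r = 3, patch_r = 1, K = 6,
                            tol = 1e-5, max_iter = 100) {
  stopifnot(fuzzifier > 1)
  d <- dim(vol)
  dom <- which(periosteal_mask)
  if (!length(dom)) stop("empty periosteal mask")
  zsc <- function(a) {
    v <- a[dom]
    s <- sd(v)
    out <- array(0, d)
    out[dom] <- if (s > 0) (v - mean(v)) / s else 0
    out
  }
  feats <- list(zsc(vol_array(vol)),
                zsc(array(as.numeric(bone_mask), d)),
                zsc(periosteal_distance))
  if (lambda > 0) {
    fbar <- nl_average_features(feats, window_r, patch_r, K)
  } else {
    fbar <- feats
  }
  X <- vapply(feats, function(a) a[dom], numeric(length(dom)))
  Xb <- vapply(fbar, function(a) a[dom], numeric(length(dom)))
  m <- fuzzifier
  nc <- 2
  # initialize centroids from the periosteal-distance feature split
  o <- order(X[, 3])
  v <- rbind(colMeans(X[o[seq_len(floor(length(dom) / 2))], , drop = FALSE]),
             colMeans(X[o[-seq_len(floor(length(dom) / 2))], , drop = FALSE]))
  obj <- numeric(0)
  converged <- FALSE
  u <- matrix(0.5, length(dom), nc)
  for (it in seq_len(max_iter)) {
    d2 <- vapply(seq_len(nc), function(c)
      rowSums(sweep(X, 2, v[c, ])^2) +
        lambda * rowSums(sweep(Xb, 2, v[c, ])^2), numeric(length(dom)))
    d2 <- pmax(d2, 1e-12)
    w <- d2^(-1 / (m - 1))
    u <- w / rowSums(w)
    um <- u^m
    for (c in seq_len(nc))
      v[c, ] <- colSums(um[, c] * (X + lambda * Xb)) /
        ((1 + lambda) * sum(um[, c]))
    J <- sum(um * d2)
    obj <- c(obj, J)
    if (it > 1 && abs(obj[it - 1] - J) <= tol * max(J, 1e-12)) {
      converged <- TRUE
      break
    }
  }
  degenerate <- sqrt(sum((v[1, ] - v[2, ])^2)) < 1e-6
  if (degenerate) converged <- FALSE
  # cortical = cluster with the smaller mean periosteal distance among its
  # hard-assigned voxels
  hard <- max.col(u, ties.method = "first")
  pd <- periosteal_distance[dom]
  mean_pd <- vapply(seq_len(nc), function(c)
    if (any(hard == c)) mean(pd[hard == c]) else Inf, numeric(1))
  cort_c <- which.min(mean_pd)
  cortical <- array(FALSE, d)
  cortical[dom[hard == cort_c]] <- TRUE
  memb <- array(0, d)
  memb[dom] <- u[, cort_c]
  list(cortical_mask = cortical,
       trabecular_mask = array(periosteal_mask & !cortical, d),
       membership_cortical = memb,
       objective = obj, converged = converged, degenerate = degenerate,
       centroids = v)
}
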