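# Group statistics: adjusted group comparisons, partial Spearman
# correlations, Fisher-Z comparison of correlations between independent
# groups, Benjamini-Hochberg FDR, and their voxel/vertex-wise (map) forms.

#' Covariate-adjusted group difference by linear regression
#'
#' Ordinary least squares of `y` on a group indicator plus covariates;
#' returns the group coefficient (difference for the second factor level,
#' or the level named `"fracture"` when present) with its two-sided t-test
#' p-value.
#'
#' @param data data frame.
#' @param y,group column names (strings) of outcome and two-level group.
#' @param covariates character vector of covariate column names.
#' @return one-row tibble: `estimate`, `se`, `statistic`, `p`, `df`, `n`.
#' @export
adjusted_group_difference <- function(data, y, group,
                                      covariates = c("age", "height",
                                                     "weight")) {
  df <- data[stats::complete.cases(data[c(y, group, covariates)]), ]
  g <- factor(df[[group]])
  if (nlevels(g) != 2) stop("group must have exactly two levels")
  if ("fracture" %in% levels(g)) g <- stats::relevel(g, ref = setdiff(levels(g), "fracture")[1])
  X <- cbind(1, as.numeric(g == levels(g)[2]),
             as.matrix(df[covariates]))
  colnames(X) <- c("(intercept)", "group", covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear design; drop: ", paste(bad, collapse = ", "))
  }
  n <- nrow(X)
  if (n <= ncol(X)) stop("too few subjects for the adjusted comparison")
  fit <- lm.fit(X, df[[y]])
  rss <- sum(fit$residuals^2)
  dfree <- n - ncol(X)
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(rss / dfree * XtXinv[2, 2])
  est <- fit$coefficients["group"]
  tstat <- est / se
  tibble(estimate = unname(est), se = se, statistic = unname(tstat),
         p = unname(2 * pt(abs(tstat), dfree, lower.tail = FALSE)),
         df = dfree, n = n)
}

# rank with average ties, NA kept
midrank <- function(x) rank(x, na.last = "keep", ties.method = "average")

# residuals of y on [1, Z]
residualize <- function(y, Z) {
  X <- cbind(1, Z)
  qr.resid(qr(X), y)
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x` and `y` (average ranks on ties), residualizes each on
#' the covariates by least squares, and correlates the residuals; the
#' p-value uses a t statistic with `n - 2 - k` degrees of freedom (`k`
#' covariates). With no covariates this is exactly the ordinary Spearman
#' correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data frame (or `NULL`).
#' @return one-row tibble: `rho`, `p`, `n`, `df`, `defined` (FALSE when a
#'   variable is constant after ranking).
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  Z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(Z)) ok <- ok & apply(is.finite(Z), 1, all)
  x <- x[ok]; y <- y[ok]
  if (!is.null(Z)) Z <- Z[ok, , drop = FALSE]
  n <- length(x)
  k <- if (is.null(Z)) 0L else ncol(Z)
  if (n <= k + 3)
    return(tibble(rho = NA_real_, p = NA_real_, n = n, df = NA_integer_,
                  defined = FALSE))
  rx <- midrank(x); ry <- midrank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(tibble(rho = NA_real_, p = NA_real_, n = n, df = NA_integer_,
                  defined = FALSE))
  if (!is.null(Z)) {
    rx <- residualize(rx, Z)
    ry <- residualize(ry, Z)
    if (sd(rx) == 0 || sd(ry) == 0)
      return(tibble(rho = NA_real_, p = NA_real_, n = n, df = NA_integer_,
                    defined = FALSE))
  }
  rho <- cor(rx, ry)
  dfree <- n - 2L - k
  tstat <- rho * sqrt(dfree / max(1 - rho^2, .Machine$double.eps))
  tibble(rho = rho, p = 2 * pt(abs(tstat), dfree, lower.tail = FALSE),
         n = n, df = dfree, defined = TRUE)
}

#' Compare two correlations with the Fisher Z transformation
#'
#' `z = (atanh(rho1) - atanh(rho2)) / sqrt(1/(n1-3-k) + 1/(n2-3-k))` with
#' `k` the number of covariates partialled out (set `df_correction = FALSE`
#' for the classic `n - 3`); two-sided normal p-value.
#'
#' @param rho1,rho2 correlations (|rho| < 1).
#' @param n1,n2 group sizes.
#' @param n_covariates covariates partialled out (default 0).
#' @param df_correction subtract `n_covariates` from each effective size.
#' @return one-row tibble: `z`, `p`, `delta_rho` (`rho1 - rho2`).
#' @export
fisher_z_compare <- function(rho1, n1, rho2, n2, n_covariates = 0,
                             df_correction = TRUE) {
  if (any(abs(c(rho1, rho2)) >= 1, na.rm = TRUE))
    stop("|rho| = 1: Fisher transform is infinite")
  k <- if (df_correction) n_covariates else 0
  e1 <- n1 - 3 - k
  e2 <- n2 - 3 - k
  if (any(c(e1, e2) <= 0)) stop("effective group size must exceed 3 + k")
  z <- (atanh(rho1) - atanh(rho2)) / sqrt(1 / e1 + 1 / e2)
  tibble(z = z, p = 2 * pnorm(abs(z), lower.tail = FALSE),
         delta_rho = rho1 - rho2)
}

#' Benjamini-Hochberg FDR significance flags
#'
#' Step-up procedure at level `q`: sort the p-values, find the largest `i`
#' with `p_(i) <= i q / m`, and flag everything at or below `p_(i)`.
#' `NA` p-values are never flagged and do not count toward `m`.
#'
#' @param p p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return logical vector of flags (empty input gives empty output).
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (!length(p)) return(logical(0))
  out <- rep(FALSE, length(p))
  ok <- !is.na(p)
  if (any(ok)) out[ok] <- p.adjust(p[ok], method = "BH") <= q
  out
}

# matrix-form partial Spearman across many locations: Y1, Y2 are n x m
# matrices (subjects x locations), Z the covariate matrix. Returns rho and
# p vectors of length m; columns with any NA or with ties collapsing to a
# constant are NA.
partial_spearman_map <- function(Y1, Y2, Z = NULL, min_frac = 0.9) {
  n_all <- nrow(Y1)
  m <- ncol(Y1)
  rho <- rep(NA_real_, m)
  pval <- rep(NA_real_, m)
  nloc <- integer(m)
  k <- if (is.null(Z)) 0L else ncol(Z)
  ok_rows <- is.finite(Y1) & is.finite(Y2)
  n_ok <- colSums(ok_rows)
  complete <- n_ok == n_all
  # fast path: locations with complete data share the covariate projector
  if (any(complete)) {
    R1 <- apply(Y1[, complete, drop = FALSE], 2, midrank)
    R2 <- apply(Y2[, complete, drop = FALSE], 2, midrank)
    if (!is.null(Z)) {
      q <- qr(cbind(1, Z))
      R1 <- qr.resid(q, R1)
      R2 <- qr.resid(q, R2)
    } else {
      R1 <- scale(R1, scale = FALSE)
      R2 <- scale(R2, scale = FALSE)
    }
    s1 <- sqrt(colSums(R1^2))
    s2 <- sqrt(colSums(R2^2))
    r <- colSums(R1 * R2) / (s1 * s2)
    r[s1 == 0 | s2 == 0] <- NA_real_
    dfree <- n_all - 2L - k
    tstat <- r * sqrt(dfree / pmax(1 - r^2, .Machine$double.eps))
    rho[complete] <- r
    pval[complete] <- 2 * pt(abs(tstat), dfree, lower.tail = FALSE)
    nloc[complete] <- n_all
  }
  # slow path: incomplete locations above the minimum-n rule
  partial_idx <- which(!complete & n_ok >= pmax(k + 4, min_frac * n_all))
  for (j in partial_idx) {
    okj <- ok_rows[, j]
    res <- partial_spearman(Y1[okj, j], Y2[okj, j],
                            if (is.null(Z)) NULL else Z[okj, , drop = FALSE])
    rho[j] <- res$rho
    pval[j] <- res$p
    nloc[j] <- res$n
  }
  list(rho = rho, p = pval, n = nloc)
}

#' Voxel/vertex-wise partial Spearman correlation map
#'
#' Computes the partial Spearman correlation of two spatially normalized
#' parametric maps at every template location within one group, adjusted
#' for the covariates (age, height, weight and shape PCs in the full
#' pipeline), and FDR-corrects the p-value map over the locations that
#' passed the minimum-n rule.
#'
#' @param maps1,maps2 n x m matrices: subjects by template locations
#'   (voxels or vertices), `NA` = undefined.
#' @param covariates data frame / matrix of per-subject covariates.
#' @param q FDR level.
#' @param min_frac minimum fraction of subjects that must be defined at a
#'   location (default 0.9); locations below it are undefined-flagged and
#'   excluded from the FDR family.
#' @return a `stat_map` list: `rho`, `p`, `significant`, `n` (per-location
#'   effective n), `n_covariates`, `q`.
#' @export
correlation_map <- function(maps1, maps2, covariates = NULL, q = 0.05,
                            min_frac = 0.9) {
  stopifnot(identical(dim(maps1), dim(maps2)))
  Z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  res <- partial_spearman_map(maps1, maps2, Z, min_frac)
  if (all(is.na(res$rho))) stop("no location has enough defined subjects")
  flags <- fdr_correct(res$p, q)
  structure(list(rho = res$rho, p = res$p, significant = flags,
                 n = res$n,
                 n_covariates = if (is.null(Z)) 0L else ncol(Z), q = q),
            class = "stat_map")
}

#' Between-group difference map of correlations (Fisher Z)
#'
#' Per-location Fisher-Z comparison of two group `stat_map`s (fracture
#' minus control convention for the reported difference), FDR-corrected
#' over the common defined domain.
#'
#' @param map_control,map_fracture `stat_map`s on the same template domain.
#' @param q FDR level.
#' @param df_correction see [fisher_z_compare()].
#' @return a `stat_map` list with `delta_rho` (fracture - control), `z`,
#'   `p`, `significant`.
#' @export
correlation_difference_map <- function(map_control, map_fracture, q = 0.05,
                                       df_correction = TRUE) {
  if (length(map_control$rho) != length(map_fracture$rho))
    stop("mismatched template domains")
  k <- if (df_correction) map_control$n_covariates else 0
  ok <- !is.na(map_control$rho) & !is.na(map_fracture$rho) &
    abs(map_control$rho) < 1 & abs(map_fracture$rho) < 1
  m <- length(map_control$rho)
  z <- rep(NA_real_, m); pv <- rep(NA_real_, m)
  e1 <- map_fracture$n[ok] - 3 - k
  e2 <- map_control$n[ok] - 3 - k
  zz <- (atanh(map_fracture$rho[ok]) - atanh(map_control$rho[ok])) /
    sqrt(1 / e1 + 1 / e2)
  z[ok] <- zz
  pv[ok] <- 2 * pnorm(abs(zz), lower.tail = FALSE)
  structure(list(delta_rho = map_fracture$rho - map_control$rho,
                 z = z, p = pv, significant = fdr_correct(pv, q),
                 n_covariates = map_control$n_covariates, q = q),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  m <- length(x$p)
  cat(sprintf("<stat_map> %d locations, %d defined, %d FDR-significant (q = %g)\n",
              m, sum(!is.na(x$p)), sum(x$significant, na.rm = TRUE), x$q))
  invisible(x)
}

#' Global partial-correlation table for a cohort
#'
#' All pairwise partial Spearman correlations of the given metric columns
#' within each group, with the between-group Fisher-Z comparison: the
#' layout of the compartmental interrelationship tables.
#'
#' @param data cohort tibble with a `group` column (`control`/`fracture`).
#' @param metrics character vector of metric column names.
#' @param covariates covariate column names.
#' @param df_correction see [fisher_z_compare()].
#' @return tibble: `var1`, `var2`, `rho_control`, `p_control`,
#'   `rho_fracture`, `p_fracture`, `p_between`.
#' @export
correlation_table <- function(data, metrics,
                              covariates = c("age", "height", "weight"),
                              df_correction = TRUE) {
  pairs <- utils::combn(metrics, 2)
  ctl <- data[data$group == "control", ]
  fx <- data[data$group == "fracture", ]
  rows <- vector("list", ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    v1 <- pairs[1, i]; v2 <- pairs[2, i]
    rc <- partial_spearman(ctl[[v1]], ctl[[v2]], ctl[covariates])
    rf <- partial_spearman(fx[[v1]], fx[[v2]], fx[covariates])
    pb <- if (isTRUE(rc$defined) && isTRUE(rf$defined) &&
              abs(rc$rho) < 1 && abs(rf$rho) < 1)
      fisher_z_compare(rc$rho, rc$n, rf$rho, rf$n,
                       length(covariates), df_correction)$p
    else NA_real_
    rows[[i]] <- tibble(var1 = v1, var2 = v2,
                        rho_control = rc$rho, p_control = rc$p,
                        rho_fracture = rf$rho, p_fracture = rf$p,
                        p_between = pb)
  }
  dplyr::bind_rows(rows)
}

#' Group-comparison table for a cohort
#'
#' Adjusted group differences for each metric column: the layout of the
#' group-comparison tables (mean +/- sd per group, adjusted p).
#'
#' @inheritParams correlation_table
#' @return tibble: `metric`, `mean_control`, `sd_control`,
#'   `mean_fracture`, `sd_fracture`, `estimate`, `p`.
#' @export
group_comparison_table <- function(data, metrics,
                                   covariates = c("age", "height",
                                                  "weight")) {
  rows <- lapply(metrics, function(m) {
    ad <- adjusted_group_difference(data, m, "group", covariates)
    ctl <- data[[m]][data$group == "control"]
    fx <- data[[m]][data$group == "fracture"]
    tibble(metric = m,
           mean_control = mean(ctl, na.rm = TRUE),
           sd_control = sd(ctl, na.rm = TRUE),
           mean_fracture = mean(fx, na.rm = TRUE),
           sd_fracture = sd(fx, na.rm = TRUE),
           estimate = ad$estimate, p = ad$p)
  })
  dplyr::bind_rows(rows)
}
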