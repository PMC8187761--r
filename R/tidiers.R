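# broom-style tidiers and ggplot2 autoplot methods for the result objects

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn correlation_map one row per template location (`rho`, `p`,
#'   `significant`, `n`).
#' @param x a `stat_map`.
#' @param ... unused.
#' @export
tidy.stat_map <- function(x, ...) {
  out <- tibble(location = seq_along(x$p))
  for (nm in intersect(c("rho", "delta_rho", "z", "p", "significant", "n"),
                       names(x)))
    out[[nm]] <- x[[nm]]
  out
}

#' @describeIn correlation_map one-row summary (defined locations, flagged
#'   fraction).
#' @export
glance.stat_map <- function(x, ...) {
  defined <- sum(!is.na(x$p))
  tibble(n_locations = length(x$p), n_defined = defined,
         n_significant = sum(x$significant, na.rm = TRUE),
         flagged_fraction = if (defined) sum(x$significant, na.rm = TRUE) /
           defined else NA_real_,
         q = x$q)
}

#' @describeIn solve_compression one-row summary of the solved model.
#' @param x an `fe_result`.
#' @param ... unused.
#' @export
glance.fe_result <- function(x, ...) {
  tibble(reaction_force = x$reaction_force, stiffness = x$stiffness,
         sed_mean = mean(x$sed), sed_max = max(x$sed),
         energy_balance = x$energy_balance,
         force_balance = x$force_balance,
         solver_iters = x$solver_iters, residual = x$residual)
}

#' @describeIn shape_pca per-subject scores in long-friendly wide form.
#' @param x a `shape_covariates`.
#' @param ... unused.
#' @export
tidy.shape_covariates <- function(x, ...) {
  out <- x$scores
  out$subject <- seq_len(nrow(out))
  dplyr::relocate(out, "subject")
}

#' @describeIn shape_pca one-row summary (components kept, variance).
#' @export
glance.shape_covariates <- function(x, ...) {
  tibble(k = x$k, k_at_target = x$k_at_target,
         variance_explained = sum(x$variance_explained))
}

#' @describeIn segment_volume one-row QC summary.
#' @param x a `compartment_segmentation`.
#' @param ... unused.
#' @export
glance.compartment_segmentation <- function(x, ...) {
  tibble(periosteal_voxels = sum(x$periosteal_mask),
         cortical_voxels = sum(x$cortical_mask),
         trabecular_voxels = sum(x$trabecular_mask),
         bone_voxels = sum(x$bone_mask),
         periosteal_threshold = x$periosteal_threshold,
         bone_threshold = x$bone_threshold,
         shell_contiguous = x$shell_contiguous)
}

#' Plot an axial slice of a volume or mask
#'
#' @param vol a [bone_volume()] or 3D array.
#' @param z slice index (default: middle).
#' @param title optional plot title.
#' @return a ggplot.
#' @export
plot_slice <- function(vol, z = NULL, title = NULL) {
  a <- if (inherits(vol, "bone_volume")) vol_array(vol) else vol
  if (is.null(z)) z <- ceiling(dim(a)[3] / 2)
  sl <- a[, , z]
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- as.numeric(sl)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title %||% sprintf("slice %d", z),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
autoplot.bone_volume <- function(object, z = NULL, ...) {
  plot_slice(object, z, "BMD (mg/cm³)")
}

#' @export
autoplot.stat_map <- function(object, ...) {
  df <- tidy(object)
  value <- if ("delta_rho" %in% names(df)) "delta_rho" else "rho"
  ggplot2::ggplot(df[!is.na(df$p), ],
                  ggplot2::aes(x = .data[[value]],
                               fill = .data$significant)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.8, position = "identity") +
    ggplot2::labs(x = value, y = "locations",
                  fill = sprintf("FDR q = %g", object$q)) +
    ggplot2::theme_minimal()
}

#' Group comparison plot of cohort metrics
#'
#' @param data cohort metric tibble with a `group` column.
#' @param metrics metric column names.
#' @return a ggplot (boxplots by group, one facet per metric).
#' @export
plot_group_metrics <- function(data, metrics) {
  long <- tidyr::pivot_longer(data[c("group", metrics)],
                              dplyr::all_of(metrics),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
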