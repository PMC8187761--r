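# volume-weighted mean local thickness of a phase, excluding voxels whose
# inscribed sphere is truncated by the axial field-of-view boundary
mean_local_thickness <- function(fg, spacing, dim3) {
  lt <- cpp_local_thickness(as.logical(fg), dim3, spacing)
  idx <- which(fg)
  z <- ((idx - 1) %/% (dim3[1] * dim3[2])) + 1
  zdist <- (pmin(z - 1, dim3[3] - z) + 0.5) * spacing[3]
  keep <- zdist >= lt[idx] / 2
  if (!any(keep)) keep <- rep(TRUE, length(idx))
  mean(lt[idx][keep])
}

#' Trabecular compartment metrics
#'
#' * `tb_bmd`: mean BMD over the trabecular mask (mg/cm^3).
#' * `tb_bvtv`: bone voxels / trabecular voxels.
#' * `tb_n`: trabecular number (1/mm), the reciprocal of the mean
#'   centre-to-centre spacing of the trabeculae: the volume-weighted mean
#'   local thickness (largest-inscribed-sphere transform) of the marrow
#'   phase plus that of the bone phase, the direct distance-transform
#'   measurement of mid-axis spacing. Voxels whose inscribed sphere is cut
#'   by the axial field-of-view boundary are excluded from the means.
#' * `tb_sp`: trabecular separation, derived as `(1 - tb_bvtv) / tb_n` (mm).
#'
#' @param vol a [bone_volume()].
#' @param seg a `compartment_segmentation` from [segment_volume()], or a list
#'   with `trabecular_mask` and `bone_mask`.
#' @return tibble with one row: `tb_bmd`, `tb_bvtv`, `tb_n`, `tb_sp`,
#'   `tb_sp_defined`.
#' @export
trabecular_metrics <- function(vol, seg) {
  sp <- vol_spacing(vol)
  trab <- seg$trabecular_mask
  if (!any(trab)) stop("empty trabecular mask")
  bone_t <- seg$bone_mask & trab
  v <- vol_array(vol)
  tb_bmd <- mean(v[trab])
  tb_bvtv <- sum(bone_t) / sum(trab)
  if (!any(bone_t)) {
    return(tibble(tb_bmd = tb_bmd, tb_bvtv = tb_bvtv, tb_n = 0,
                  tb_sp = NA_real_, tb_sp_defined = FALSE))
  }
  marrow <- trab & !bone_t
  if (!any(marrow)) { # solid bone: no inter-trabecular space
    return(tibble(tb_bmd = tb_bmd, tb_bvtv = tb_bvtv, tb_n = NA_real_,
                  tb_sp = NA_real_, tb_sp_defined = FALSE))
  }
  sep_mean <- mean_local_thickness(marrow, sp, dim(vol))
  th_mean <- mean_local_thickness(bone_t, sp, dim(vol))
  tb_n <- 1 / (sep_mean + th_mean)
  tb_sp <- (1 - tb_bvtv) / tb_n
  tibble(tb_bmd = tb_bmd, tb_bvtv = tb_bvtv, tb_n = tb_n, tb_sp = tb_sp,
         tb_sp_defined = TRUE)
}

# perimeter (mm) of the 0.5-level contour of a lightly smoothed binary slice
slice_perimeter <- function(slice, spacing2) {
  d <- dim(slice)
  a <- array(as.numeric(slice), c(d, 1))
  k <- gaussian_kernel3(max(spacing2), c(spacing2, 1))
  k <- k[, , (dim(k)[3] + 1) / 2, drop = FALSE]
  k <- k / sum(k)
  sm <- fft_convolve3(a, k)[, , 1, drop = TRUE]
  cl <- grDevices::contourLines(x = (seq_len(d[1]) - 1) * spacing2[1],
                                y = (seq_len(d[2]) - 1) * spacing2[2],
                                z = sm, levels = 0.5)
  if (!length(cl)) return(0)
  sum(vapply(cl, function(p) {
    dx <- diff(c(p$x, p$x[1]))
    dy <- diff(c(p$y, p$y[1]))
    sum(sqrt(dx^2 + dy^2))
  }, numeric(1)))
}

#' Cortical compartment metrics
#'
#' `ct_bmd` is the mean BMD over the cortical mask; `ct_th` is the annular
#' mean thickness: cortical volume divided by the periosteal lateral surface
#' area (per-slice outer-contour perimeter integrated over slice thickness).
#'
#' @inheritParams trabecular_metrics
#' @return tibble with one row: `ct_bmd`, `ct_th`.
#' @export
cortical_metrics <- function(vol, seg) {
  sp <- vol_spacing(vol)
  cort <- seg$cortical_mask
  if (!any(cort)) stop("empty cortical mask")
  v <- vol_array(vol)
  ct_bmd <- mean(v[cort])
  vol_ct <- sum(cort) * prod(sp)
  perims <- vapply(seq_len(dim(vol)[3]), function(z)
    slice_perimeter(seg$periosteal_mask[, , z], sp[seq_len(2)]), numeric(1))
  area <- sum(perims) * sp[3]
  tibble(ct_bmd = ct_bmd, ct_th = if (area > 0) vol_ct / area else NA_real_)
}

#' Standard compartmental metrics for one subject
#'
#' Convenience wrapper combining [trabecular_metrics()] and
#' [cortical_metrics()].
#'
#' @inheritParams trabecular_metrics
#' @return one-row tibble: `tb_bmd`, `tb_bvtv`, `tb_n`, `tb_sp`, `ct_bmd`,
#'   `ct_th` (and `tb_sp_defined`).
#' @export
standard_metrics <- function(vol, seg) {
  dplyr::bind_cols(trabecular_metrics(vol, seg), cortical_metrics(vol, seg))
}

#' Standard metrics for every subject of a cohort
#'
#' Segments each subject's volume and computes the standard compartmental
#' metrics; optionally also runs the micro-FE compression model for
#' `mufea_stiffness` and `mufea_fl`. Subjects with motion grade > 3 are
#' retained here and excluded by the pipeline bookkeeping.
#'
#' @param cohort tibble from [make_cohort()] with a `volume` list-column.
#' @param fea if `TRUE`, also compute micro-FE stiffness and failure load.
#' @param calibrate `"cohort"` (default) calibrates the periosteal and bone
#'   thresholds once, on a reference subject, and applies them to everyone
#'   -- per-subject self-calibration would partially compensate away true
#'   density/structure differences; `"subject"` calibrates each volume
#'   independently.
#' @param ... passed to [segment_volume()].
#' @return the cohort tibble (minus the volume column) with metric columns
#'   appended.
#' @export
cohort_metrics <- function(cohort, fea = FALSE,
                           calibrate = c("cohort", "subject"), ...) {
  calibrate <- match.arg(calibrate)
  fixed <- list()
  if (calibrate == "cohort" && nrow(cohort) > 1) {
    fixed <- cohort_thresholds(cohort$volume, ...)
  }
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    vol <- cohort$volume[[i]]
    seg <- do.call(segment_volume, c(list(vol = vol), fixed, list(...)))
    met <- standard_metrics(vol, seg)
    if (fea) {
      model <- build_fe_model(seg, spacing = vol_spacing(vol))
      res <- solve_compression(model)
      met$mufea_stiffness <- res$stiffness
      met$mufea_fl <- failure_load(res, model)
    }
    rows[[i]] <- met
  }
  dplyr::bind_cols(
    dplyr::select(cohort, -dplyr::any_of(c("volume", "phantom",
                                           "gt_bvtv_profile",
                                           "gt_bmd_profile"))),
    dplyr::bind_rows(rows))
}


# median thresholds over a handful of reference subjects: stable cohort
# calibration that no single subject's idiosyncrasy can dominate
cohort_thresholds <- function(volumes, n_ref = 5, ...) {
  idx <- unique(round(seq(1, length(volumes), length.out = min(n_ref,
                                                               length(volumes)))))
  refs <- lapply(idx, function(i) segment_volume(volumes[[i]], ...))
  list(threshold = median(vapply(refs, `[[`, numeric(1),
                                 "periosteal_threshold")),
       bone_threshold = median(vapply(refs, `[[`, numeric(1),
                                      "bone_threshold")),
       solid_threshold = median(vapply(refs, `[[`, numeric(1),
                                       "solid_threshold")))
}
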