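# Pipeline orchestration: synth -> segment -> metrics (-> FE) -> maps ->
# (normalize ->) statistics, with config validation, stage caching and a
# run manifest.

default_config <- function() {
  list(
    output_dir = "bonespm_out",
    seed = 1L,
    motion_grade_max = 3,
    save_volumes = FALSE,
    stages = list(synth = TRUE, segment = TRUE, metrics = TRUE,
                  fea = FALSE, maps = TRUE, surface = TRUE,
                  normalize = FALSE, stats = TRUE),
    cohort = list(n_control = 12, n_fracture = 12),
    phantom = list(),
    segmentation = list(threshold = NULL, closing_radius = 3,
                        bone_threshold = NULL, min_cortex_voxels = 3,
                        solid_threshold = NULL),
    fea = list(elastic_modulus = 6829, poisson_ratio = 0.3,
               applied_strain = 0.01, lateral = "free",
               critical_strain = 0.007, critical_volume_fraction = 0.02),
    maps = list(radius = 11, radius_1n = 5, erosion_depth = NULL),
    surface = list(n_angles = 48),
    normalize = list(deformable = TRUE, demons_iter = 20,
                     demons_sigma = 2),
    stats = list(q = 0.05, covariates = c("age", "height", "weight"),
                 min_frac = 0.9, df_correction = TRUE))
}

#' Pipeline configuration
#'
#' Builds and validates the full pipeline configuration. Every module's
#' parameters live under namespaced keys (`cohort`, `phantom`,
#' `segmentation`, `fea`, `maps`, `surface`, `normalize`, `stats`); unknown
#' keys are rejected. Defaults carry the published analysis constants
#' (kernel radii 11/5 voxels, E = 6829 MPa, nu = 0.3, 1 % strain,
#' q = 0.05).
#'
#' @param ... overrides of the default configuration (named scalars or
#'   named lists for the namespaced keys).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- default_config()
  over <- list(...)
  nested <- c("stages", "cohort", "phantom", "segmentation", "fea", "maps",
              "surface", "normalize", "stats")
  for (nm in names(over)) {
    if (!nm %in% names(cfg))
      stop("unknown configuration key: ", nm)
    if (nm %in% nested) {
      sub <- over[[nm]]
      if (nm %in% c("cohort", "phantom")) {
        # validated by cohort_spec()/phantom_spec() at run time
        cfg[[nm]] <- utils::modifyList(cfg[[nm]], sub)
        next
      }
      bad <- setdiff(names(sub), names(cfg[[nm]]))
      if (length(bad))
        stop(sprintf("unknown key%s under '%s': %s",
                     if (length(bad) > 1) "s" else "", nm,
                     paste(bad, collapse = ", ")))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], sub)
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic cohort
#' (or one supplied via `cohort`). Subjects with motion grade above
#' `motion_grade_max` are excluded before any analysis and counted in the
#' manifest. Stages whose parameter hash matches a previous run's outputs
#' on disk are skipped.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional cohort tibble (from [make_cohort()]); when `NULL`
#'   the synth stage generates one.
#' @return a `run_manifest` list: per-stage status tibble, exclusion count,
#'   output paths, and the in-memory results (`metrics`, `tables`,
#'   `stat_maps` when computed).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  t_stage <- function(expr) {
    t0 <- proc.time()[3]
    v <- force(expr)
    list(value = v, wall = proc.time()[3] - t0)
  }
  log_stage <- function(name, status, wall = NA_real_, note = "") {
    manifest[[name]] <<- tibble(stage = name, status = status,
                                wall_s = round(wall, 2), note = note)
  }
  results <- list()

  ## synth ------------------------------------------------------------
  if (is.null(cohort)) {
    if (!config$stages$synth) stop("no cohort supplied and synth disabled")
    cs <- do.call(cohort_spec,
                  c(config$cohort,
                    list(base_spec = do.call(phantom_spec, config$phantom),
                         seed = config$seed)))
    st <- t_stage(make_cohort(cs))
    cohort <- st$value
    log_stage("synth", "done", st$wall,
              sprintf("%d subjects", nrow(cohort)))
  } else {
    log_stage("synth", "skipped (cohort supplied)")
  }

  ## exclusion bookkeeping --------------------------------------------
  excluded <- sum(cohort$motion_grade > config$motion_grade_max)
  included <- cohort[cohort$motion_grade <= config$motion_grade_max, ]
  log_stage("exclusion", "done", 0,
            sprintf("%d of %d excluded (motion grade > %d)",
                    excluded, nrow(cohort), config$motion_grade_max))

  ## segment + metrics (+ fea + maps + surface) per subject ------------
  metrics_path <- file.path(config$output_dir, "metrics.csv")
  hash <- config_hash(list(config[c("seed", "cohort", "phantom",
                                    "segmentation", "fea", "maps",
                                    "surface", "stages")],
                           included$id))
  hash_path <- file.path(config$output_dir, "metrics.hash")
  cached <- file.exists(metrics_path) && file.exists(hash_path) &&
    readLines(hash_path, warn = FALSE)[1] == hash
  if (cached) {
    metrics <- as_tibble(utils::read.csv(metrics_path))
    log_stage("metrics", "skipped (cache hit)")
  } else {
    t0 <- proc.time()[3]
    rows <- vector("list", nrow(included))
    seg_args <- config$segmentation
    if (is.null(seg_args$threshold) && is.null(seg_args$bone_threshold) &&
        nrow(included) > 1) {
      # calibrate thresholds once on the first subject and hold them fixed
      # across the cohort (per-subject self-calibration would absorb true
      # group differences)
      thr <- do.call(cohort_thresholds,
                     c(list(volumes = included$volume), seg_args))
      seg_args$threshold <- thr$threshold
      seg_args$bone_threshold <- thr$bone_threshold
      seg_args$solid_threshold <- thr$solid_threshold
    }
    for (i in seq_len(nrow(included))) {
      vol <- included$volume[[i]]
      seg <- do.call(segment_volume, c(list(vol = vol), seg_args))
      row <- standard_metrics(vol, seg)
      sed_map <- NULL
      if (config$stages$fea) {
        model <- build_fe_model(seg, spacing = vol_spacing(vol),
                                elastic_modulus = config$fea$elastic_modulus,
                                poisson_ratio = config$fea$poisson_ratio,
                                applied_strain = config$fea$applied_strain,
                                lateral = config$fea$lateral)
        res <- solve_compression(model)
        row$mufea_stiffness <- res$stiffness
        row$mufea_fl <- failure_load(res, model,
                                     config$fea$critical_strain,
                                     config$fea$critical_volume_fraction)
        sed_map <- fe_sed_map(model, res)
      }
      if (config$stages$maps) {
        er <- config$maps$erosion_depth %||% config$maps$radius
        vm <- voxel_map_set(vol, seg, sed_map = sed_map,
                            radius = config$maps$radius,
                            radius_1n = config$maps$radius_1n,
                            erosion_depth = er)
        row$h_tb_bmd <- mean(vm$h_tb_bmd, na.rm = TRUE)
        row$l_tb_bvtv <- mean(vm$l_tb_bvtv, na.rm = TRUE)
        row$h_tb_1n <- mean(vm$h_tb_1n, na.rm = TRUE)
        if (!is.null(vm$h_tb_sed))
          row$h_tb_sed <- mean(vm$h_tb_sed, na.rm = TRUE)
      }
      if (config$stages$surface) {
        sm <- surface_map_set(vol, seg, sed_map = sed_map,
                              n_angles = config$surface$n_angles)
        row$surf_app_ct_th <- mean(sm$values$surf_app_ct_th, na.rm = TRUE)
        row$surf_ct_sit <- mean(sm$values$surf_ct_sit, na.rm = TRUE)
        row$surf_ct_bmd <- mean(sm$values$surf_ct_bmd, na.rm = TRUE)
        if ("surf_ct_sed" %in% names(sm$values))
          row$surf_ct_sed <- mean(sm$values$surf_ct_sed, na.rm = TRUE)
      }
      rows[[i]] <- row
    }
    meta <- dplyr::select(included, -dplyr::any_of(c(
      "volume", "phantom", "gt_bvtv_profile", "gt_bmd_profile")))
    metrics <- dplyr::bind_cols(meta, dplyr::bind_rows(rows))
    utils::write.csv(metrics, metrics_path, row.names = FALSE)
    writeLines(hash, hash_path)
    log_stage("metrics", "done", proc.time()[3] - t0,
              sprintf("%d subjects", nrow(metrics)))
  }
  results$metrics <- metrics

  ## statistics tables -------------------------------------------------
  if (config$stages$stats) {
    t0 <- proc.time()[3]
    cov <- config$stats$covariates
    std_cols <- intersect(c("tb_bmd", "tb_bvtv", "tb_n", "tb_sp",
                            "ct_bmd", "ct_th", "mufea_stiffness",
                            "mufea_fl"), names(metrics))
    map_cols <- intersect(c("h_tb_bmd", "l_tb_bvtv", "h_tb_1n", "h_tb_sed",
                            "surf_ct_bmd", "surf_app_ct_th", "surf_ct_sit",
                            "surf_ct_sed"), names(metrics))
    tables <- list()
    both_groups <- length(unique(metrics$group)) == 2 &&
      all(table(metrics$group) >= 4)
    if (both_groups) {
      tables$standard_comparison <-
        group_comparison_table(metrics, std_cols, cov)
      tables$standard_correlations <-
        correlation_table(metrics, std_cols, cov,
                          config$stats$df_correction)
      if (length(map_cols)) {
        tables$maps_comparison <-
          group_comparison_table(metrics, map_cols, cov)
        tables$maps_correlations <-
          correlation_table(metrics, map_cols, cov,
                            config$stats$df_correction)
        if ("mufea_fl" %in% names(metrics)) {
          fl <- lapply(map_cols, function(m) {
            ctl <- metrics[metrics$group == "control", ]
            fx <- metrics[metrics$group == "fracture", ]
            rc <- partial_spearman(ctl[[m]], ctl$mufea_fl, ctl[cov])
            rf <- partial_spearman(fx[[m]], fx$mufea_fl, fx[cov])
            pb <- if (isTRUE(rc$defined) && isTRUE(rf$defined))
              fisher_z_compare(rc$rho, rc$n, rf$rho, rf$n, length(cov),
                               config$stats$df_correction)$p else NA_real_
            tibble(metric = m, rho_control = rc$rho, p_control = rc$p,
                   rho_fracture = rf$rho, p_fracture = rf$p,
                   p_between = pb)
          })
          tables$fl_correlations <- dplyr::bind_rows(fl)
        }
      }
      for (nm in names(tables))
        utils::write.csv(tables[[nm]],
                         file.path(config$output_dir,
                                   paste0("table_", nm, ".csv")),
                         row.names = FALSE)
      log_stage("stats", "done", proc.time()[3] - t0,
                sprintf("%d tables", length(tables)))
    } else {
      log_stage("stats", "unavailable", proc.time()[3] - t0,
                "need two groups with >= 4 subjects each")
    }
    results$tables <- tables
  }

  structure(list(stages = dplyr::bind_rows(manifest),
                 excluded = excluded,
                 config_hash = config_hash(config),
                 output_dir = config$output_dir,
                 results = results),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  print(as.data.frame(x$stages), row.names = FALSE)
  invisible(x)
}

#' Human-readable pipeline report
#'
#' Renders the group-comparison and correlation tables of a finished run;
#' missing outputs are listed, not fatal.
#'
#' @param manifest a `run_manifest` from [run_pipeline()].
#' @return the report lines, invisibly (also printed).
#' @export
pipeline_report <- function(manifest) {
  out <- c("== bonespm pipeline report ==",
           sprintf("output dir: %s", manifest$output_dir),
           sprintf("excluded subjects (motion): %d", manifest$excluded),
           "", "stages:",
           utils::capture.output(print(as.data.frame(manifest$stages),
                                       row.names = FALSE)))
  tables <- manifest$results$tables
  expected <- c("standard_comparison", "standard_correlations",
                "maps_comparison", "maps_correlations", "fl_correlations")
  for (nm in expected) {
    out <- c(out, "", sprintf("-- %s --", nm))
    if (is.null(tables[[nm]])) {
      out <- c(out, "(unavailable)")
    } else {
      out <- c(out, utils::capture.output(
        print(as.data.frame(tables[[nm]]), row.names = FALSE,
              digits = 3)))
    }
  }
  cat(out, sep = "\n")
  invisible(out)
}

#' Validate a directory of volumes against a cohort manifest
#'
#' Checks spacing isotropy, slice count, calibration-range plausibility and
#' covariate completeness; emits one pass/fail row per subject.
#'
#' @param dir directory containing `manifest.csv` and the NIfTI volumes it
#'   lists (column `path`).
#' @param expected_slices required slice count (`NA` skips the check).
#' @param bmd_range plausible BMD range (mg/cm^3).
#' @return tibble: `id`, `pass`, `reason`.
#' @export
validate_inputs <- function(dir, expected_slices = NA,
                            bmd_range = c(-500, 2500)) {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path)) stop("no manifest.csv in ", dir)
  mf <- utils::read.csv(mf_path)
  rows <- vector("list", nrow(mf))
  for (i in seq_len(nrow(mf))) {
    id <- mf$id[i]
    reasons <- character(0)
    for (cv in c("age", "height", "weight"))
      if (!cv %in% names(mf) || is.na(mf[[cv]][i]))
        reasons <- c(reasons, sprintf("missing %s covariate", cv))
    path <- file.path(dir, mf$path[i])
    if (!file.exists(path)) {
      reasons <- c(reasons, "volume file missing")
    } else {
      vol <- tryCatch(read_volume(path), error = function(e) e)
      if (inherits(vol, "error")) {
        reasons <- c(reasons, sprintf("malformed NIfTI (%s): %s",
                                      basename(path),
                                      conditionMessage(vol)))
      } else {
        sp <- vol_spacing(vol)
        if (diff(range(sp)) > 1e-6 * mean(sp))
          reasons <- c(reasons, "anisotropic")
        if (!is.na(expected_slices) && dim(vol)[3] != expected_slices)
          reasons <- c(reasons, sprintf("expected %d slices, found %d",
                                        expected_slices, dim(vol)[3]))
        rng <- range(vol, na.rm = TRUE)
        if (rng[1] < bmd_range[1] || rng[2] > bmd_range[2])
          reasons <- c(reasons, "BMD outside calibration range")
      }
    }
    rows[[i]] <- tibble(id = id, pass = !length(reasons),
                        reason = paste(reasons, collapse = "; "))
  }
  dplyr::bind_rows(rows)
}
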