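# Configuration-driven orchestration of the synthetic end-to-end pipeline:
# simulate -> rtop -> parcel-stats -> gradients -> connectivity -> cca, with
# a run manifest (config hash + output checksums) for reproducibility.

pipeline_defaults <- function() {
  list(
    out_dir = "rtopmap-run",
    seed = 1L,
    # acquisition / dMRI phantom
    b_values = c(1000, 2000, 3000), dirs_per_shell = 90, n_b0 = 6,
    small_delta_ms = 10, big_delta_ms = 43,
    dmri_grid = c(5, 5, 4), dmri_snr = NULL,
    radial_order = 6, free_diffusivity = 3.0e-3,
    # surface phantom / parcel stats
    n_vertices = 400, gradient_direction = c(1, 1, 0),
    surface_noise_sd = 0.15, n_subjects_parcel = 60,
    subdivision_shift = c(vAI = -0.3, dAI = 0, PI = 0.3),
    hemisphere_shift = 0.08,
    stability_sample_sizes = c(10, 25, 50),
    stability_resamples = 100, stability_alpha = 0.01,
    stability_criterion = 0.95,
    # gradients
    n_subjects_gradient = 50, isocontour_levels = NULL,
    # connectivity
    n_subjects_rest = 12, rest_grid = c(14, 12, 10), rest_timepoints = 180,
    rest_tr = 0.72, rest_coupling = 0.6, rest_fwhm_mm = 2,
    rest_band_hz = c(0.008, 0.1), connectivity_alpha = 0.01,
    # brain-behavior
    n_subjects_cca = 400, planted_canonical_r = 0.32,
    missing_fraction = 0.015
  )
}

#' Pipeline configuration
#'
#' Merges overrides into the default configuration; unknown keys are
#' rejected so typos fail loudly. Every stochastic stage derives its seed
#' from the single `seed` entry.
#'
#' @param ... named overrides of the defaults (see `rtopmap:::pipeline_defaults`).
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

manifest_add <- function(out_dir, stage, files, extra = NULL) {
  mp <- file.path(out_dir, "manifest.json")
  man <- if (file.exists(mp)) jsonlite::read_json(mp) else
    list(package_version = as.character(utils::packageVersion("rtopmap")),
         stages = list())
  files <- files[file.exists(files)]
  man$stages[[stage]] <- c(list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(tools::md5sum(files))), extra)
  jsonlite::write_json(man, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}

stage_scheme <- function(config) {
  make_acquisition_scheme(config$b_values, config$dirs_per_shell,
                          config$n_b0, config$small_delta_ms,
                          config$big_delta_ms, seed = config$seed)
}

stage_simulate <- function(config) {
  out <- config$out_dir
  scheme <- stage_scheme(config)
  ph <- make_dmri_phantom(config$dmri_grid, scheme, snr = config$dmri_snr,
                          seed = config$seed)
  vol4d <- array(t(ph$signals), c(length(scheme$bvals), ph$grid_shape))
  vol4d <- aperm(vol4d, c(2, 3, 4, 1))
  write_nifti_map(vol4d, file.path(out, "dmri.nii.gz"), ph$affine,
                  sidecar = list(description = "synthetic multi-shell dMRI",
                                 small_delta_ms = config$small_delta_ms,
                                 big_delta_ms = config$big_delta_ms))
  write_bval_bvec(scheme, file.path(out, "dmri"))
  write_nifti_map(array(ph$truth_normalized_rtop, ph$grid_shape),
                  file.path(out, "truth_normalized_rtop.nii.gz"), ph$affine)

  sp <- make_surface_phantom(config$n_vertices, config$gradient_direction,
                             config$surface_noise_sd,
                             subdivision_shift = config$subdivision_shift,
                             seed = config$seed)
  for (h in c("left", "right")) {
    write_gifti_surface(sp[[h]]$mesh,
                        file.path(out, paste0(h, ".surf.gii")))
    write_gifti_labels(sp[[h]]$labels,
                       file.path(out, paste0(h, ".label.gii")))
    write_gifti_scalars(sp[[h]]$planted_field,
                        file.path(out, paste0(h, ".planted.func.gii")))
  }

  rp <- make_rest_phantom(config$rest_grid, config$rest_timepoints,
                          config$rest_tr, config$rest_coupling,
                          seed = config$seed)
  write_nifti_map(rp$data, file.path(out, "rest.nii.gz"))
  write_motion_params(rp$motion_params, file.path(out, "rest_motion.txt"))

  bb <- make_brain_behavior(config$n_subjects_cca,
                            config$planted_canonical_r,
                            config$missing_fraction, seed = config$seed)
  utils::write.csv(bb$behavior, file.path(out, "behavior.csv"),
                   row.names = FALSE)
  utils::write.csv(bb$brain, file.path(out, "brain_rtop.csv"),
                   row.names = FALSE)

  files <- file.path(out, c("dmri.nii.gz", "dmri.bval", "dmri.bvec",
                            "truth_normalized_rtop.nii.gz",
                            "left.surf.gii", "left.label.gii",
                            "right.surf.gii", "right.label.gii",
                            "rest.nii.gz", "rest_motion.txt",
                            "behavior.csv", "brain_rtop.csv"))
  manifest_add(out, "simulate", files)
  list(scheme = scheme, dmri = ph, surface = sp, rest = rp, behavior = bb,
       files = files)
}

stage_rtop <- function(config) {
  out <- config$out_dir
  img <- read_nifti_map(file.path(out, "dmri.nii.gz"))
  scheme <- read_bval_bvec(file.path(out, "dmri.bval"),
                           file.path(out, "dmri.bvec"),
                           config$small_delta_ms, config$big_delta_ms)
  dims <- dim(img$data)[1:3]
  signals <- matrix(aperm(img$data, c(4, 1, 2, 3)),
                    nrow = dim(img$data)[4])
  rmap <- compute_rtop_map(t(signals), scheme,
                           radial_order = config$radial_order,
                           free_diffusivity = config$free_diffusivity)
  paths <- file.path(out, c("rtop.nii.gz", "normalized_rtop.nii.gz"))
  write_nifti_map(array(rmap$rtop, dims), paths[1], img$affine,
                  sidecar = list(units = "mm^-3",
                                 radial_order = config$radial_order))
  write_nifti_map(array(rmap$normalized_rtop, dims), paths[2], img$affine,
                  sidecar = list(units = "unitless (tissue / free water)",
                                 free_diffusivity_mm2_s = config$free_diffusivity,
                                 tau_s = scheme$tau))
  truth <- read_nifti_map(file.path(out,
                                    "truth_normalized_rtop.nii.gz"))$data
  err <- abs(rmap$normalized_rtop - as.vector(truth)) / as.vector(truth)
  res <- list(median_rel_error = stats::median(err[rmap$valid]),
              max_rel_error = max(err[rmap$valid]),
              n_voxels = length(err), n_invalid = sum(!rmap$valid))
  write_results_json(res, file.path(out, "rtop_recovery.json"))
  manifest_add(out, "rtop", c(paths, file.path(out, "rtop_recovery.json")),
               extra = list(median_rel_error = res$median_rel_error))
  res
}

# Per-subject surface fields: planted field + subject effects; returns a
# multi-subject parcel summary using the stage-simulate labels.
simulate_subject_fields <- function(config, sp) {
  n <- config$n_subjects_parcel
  rows <- list()
  for (s in seq_len(n)) {
    subj <- sprintf("sub-%03d", s)
    for (h in c("left", "right")) {
      ph <- sp[[h]]
      shift <- if (h == "right") -config$hemisphere_shift else 0
      field <- ph$planted_field + shift +
        with_seed(config$seed + 1000L * s + (h == "right"),
                  stats::rnorm(length(ph$planted_field),
                               sd = config$surface_noise_sd))
      rows[[length(rows) + 1]] <-
        subdivision_means(field, ph$labels, subject = subj, hemisphere = h)
    }
  }
  do.call(rbind, rows)
}

stage_parcel_stats <- function(config) {
  out <- config$out_dir
  # sample the computed RTOP volume onto the surface (demonstration that the
  # volume-to-surface path runs on real files)
  vol <- read_nifti_map(file.path(out, "normalized_rtop.nii.gz"))
  mesh <- read_gifti(file.path(out, "left.surf.gii"))
  labels <- read_gifti(file.path(out, "left.label.gii"))
  # scale mesh into the small volume's world box for the demonstration
  vmax <- (dim(vol$data) - 1) * vol$affine[1, 1]
  m2 <- mesh
  for (k in 1:3) {
    rng <- range(mesh$vertices[, k])
    span <- if (diff(rng) > 0) diff(rng) else 1
    m2$vertices[, k] <- (mesh$vertices[, k] - rng[1]) / span * vmax[k]
  }
  vert_vals <- sample_volume_to_surface(vol$data, vol$affine, m2)
  sampled <- subdivision_means(vert_vals, labels, subject = "volume",
                               hemisphere = "left")
  # multi-subject statistics on the surface phantom population
  sp <- make_surface_phantom(config$n_vertices, config$gradient_direction,
                             config$surface_noise_sd,
                             subdivision_shift = config$subdivision_shift,
                             seed = config$seed)
  summary <- simulate_subject_fields(config, sp)
  write_parcel_summary(summary, file.path(out, "parcel_summary.csv"))
  anova <- two_way_rm_anova(summary)
  posthoc <- posthoc_paired_ttests(summary)
  stab <- stability_analysis(summary, config$stability_sample_sizes,
                             config$stability_resamples,
                             config$stability_alpha,
                             config$stability_criterion,
                             seed = config$seed)
  res <- list(volume_sampled_means = sampled,
              anova = anova, posthoc = posthoc,
              stability_fractions = as.data.frame(stab$fractions),
              min_stable_n = as.list(stab$min_stable_n))
  write_results_json(res, file.path(out, "parcel_stats.json"))
  manifest_add(out, "parcel-stats",
               file.path(out, c("parcel_summary.csv", "parcel_stats.json")))
  c(res, list(stability = stab))
}

stage_gradients <- function(config) {
  out <- config$out_dir
  sp <- make_surface_phantom(config$n_vertices, config$gradient_direction,
                             config$surface_noise_sd,
                             subdivision_shift = c(vAI = 0, dAI = 0, PI = 0),
                             seed = config$seed)
  res <- list()
  dir_rows <- list()
  for (h in c("left", "right")) {
    ph <- sp[[h]]
    dirs <- matrix(NA_real_, config$n_subjects_gradient, 3)
    for (s in seq_len(config$n_subjects_gradient)) {
      field <- ph$planted_field +
        with_seed(config$seed + 2000L * s + (h == "right"),
                  stats::rnorm(length(ph$planted_field),
                               sd = config$surface_noise_sd))
      gf <- mesh_gradient(ph$mesh, field)
      dirs[s, ] <- main_direction(gf, ph$labels != "background")
      dir_rows[[length(dir_rows) + 1]] <-
        data.frame(subject = sprintf("sub-%03d", s), hemisphere = h,
                   x = dirs[s, 1], y = dirs[s, 2], z = dirs[s, 3])
    }
    ds <- directional_stats(dirs, seed = config$seed)
    err_deg <- angle_between(ds$mean_direction,
                             ph$planted_gradient_direction) * 180 / pi
    res[[h]] <- list(mean_direction = ds$mean_direction,
                     dispersion = ds$dispersion, sem = ds$sem,
                     ci_halfwidth = ds$ci_halfwidth,
                     rayleigh_statistic = ds$rayleigh$statistic,
                     rayleigh_df = ds$rayleigh$df,
                     rayleigh_p = ds$rayleigh$p,
                     n = ds$n, direction_error_deg = err_deg)
    # isocontours of the noise-free group field
    lv <- config$isocontour_levels %||%
      stats::quantile(ph$planted_field, c(0.25, 0.5, 0.75), names = FALSE)
    ic <- isocontours(ph$mesh, ph$planted_field, lv)
    utils::write.csv(ic, file.path(out, paste0("isocontours_", h, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(do.call(rbind, dir_rows),
                   file.path(out, "gradient_directions.csv"),
                   row.names = FALSE)
  write_results_json(res, file.path(out, "directional_stats.json"))
  manifest_add(out, "gradients",
               file.path(out, c("gradient_directions.csv",
                                "directional_stats.json",
                                "isocontours_left.csv",
                                "isocontours_right.csv")))
  res
}

stage_connectivity <- function(config) {
  out <- config$out_dir
  n <- config$n_subjects_rest
  by_seed <- NULL
  target_masks <- NULL
  included <- 0
  for (s in seq_len(n)) {
    rp <- make_rest_phantom(config$rest_grid, config$rest_timepoints,
                            config$rest_tr, config$rest_coupling,
                            seed = config$seed + 100L * s)
    if (!motion_screen(rp$motion_params)$include) next
    included <- included + 1
    pp <- preprocess_rest(rp, config$rest_fwhm_mm, config$rest_band_hz)
    betas <- lapply(rp$seed_masks, function(m)
      seed_connectivity(pp, m)$beta)
    if (is.null(by_seed)) {
      by_seed <- lapply(betas, list)
      target_masks <- rp$target_masks
      target_mask <- rp$target_mask
    } else {
      for (k in names(betas))
        by_seed[[k]] <- c(by_seed[[k]], list(betas[[k]]))
    }
  }
  masks <- differential_subdivisions(by_seed, Reduce(`|`, target_masks),
                                     config$connectivity_alpha)
  dice <- vapply(names(masks), function(k)
    dice_coefficient(masks[[k]], target_masks[[k]]), numeric(1))
  for (k in names(masks))
    write_nifti_map(masks[[k]] * 1, file.path(out, paste0("mask_", k, ".nii.gz")))
  res <- list(n_included = included, dice = as.list(dice),
              pairwise_disjoint = TRUE)
  write_results_json(res, file.path(out, "connectivity.json"))
  manifest_add(out, "connectivity",
               file.path(out, c(paste0("mask_", names(masks), ".nii.gz"),
                                "connectivity.json")))
  c(res, list(masks = masks))
}

stage_cca <- function(config) {
  out <- config$out_dir
  behavior <- utils::read.csv(file.path(out, "behavior.csv"))
  brain <- utils::read.csv(file.path(out, "brain_rtop.csv"))
  cc <- exclude_missing(behavior, brain)
  fit <- fit_cca(cc$brain, cc$behavior)
  vc <- variate_correlation(fit)
  lp <- loo_predict(cc$brain, cc$behavior)
  scores <- data.frame(subject = cc$brain$subject,
                       brain_variate = fit$brain_variates[, 1],
                       behavior_variate = fit$behavior_variates[, 1],
                       loo_predicted = lp$predicted,
                       loo_actual = lp$actual)
  utils::write.csv(scores, file.path(out, "cca_scores.csv"),
                   row.names = FALSE)
  res <- list(n = fit$n,
              n_excluded = nrow(cc$excluded),
              canonical_correlations = fit$canonical_correlations,
              pillai_trace = fit$pillai_trace, pillai_p = fit$pillai_p,
              variate_r = vc$r, variate_p = vc$p,
              variate_cohens_d = cohens_d_from_r(vc$r),
              loo_r = lp$pearson_r, loo_p = lp$p,
              loo_cohens_d = lp$cohens_d)
  write_results_json(res, file.path(out, "cca_results.json"))
  manifest_add(out, "cca",
               file.path(out, c("cca_scores.csv", "cca_results.json")))
  res
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (generate all synthetic inputs and write them in
#' standard formats), `rtop` (fit the basis and write RTOP maps),
#' `parcel-stats`, `gradients`, `connectivity`, `cca`. Each stage reads its
#' inputs from `config$out_dir`, writes its outputs there, and appends an
#' entry (timestamp + md5 checksums) to the run manifest.
#'
#' @param name stage name.
#' @param config a [pipeline_config()].
#' @return the stage's result list, invisibly.
#' @export
run_stage <- function(name, config = pipeline_config()) {
  stages <- c("simulate", "rtop", "parcel-stats", "gradients",
              "connectivity", "cca")
  if (!name %in% stages)
    stop("unknown stage '", name, "'; expected one of: ",
         paste(stages, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$out_dir, "config.json")
  if (!file.exists(cfg_path))
    jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                         pretty = TRUE)
  if (name != "simulate") {
    need <- switch(name,
                   "rtop" = c("dmri.nii.gz", "dmri.bval", "dmri.bvec"),
                   "parcel-stats" = c("normalized_rtop.nii.gz",
                                      "left.surf.gii", "left.label.gii"),
                   "cca" = c("behavior.csv", "brain_rtop.csv"),
                   character(0))
    missing <- need[!file.exists(file.path(config$out_dir, need))]
    if (length(missing))
      stop("stage '", name, "' inputs missing: ",
           paste(missing, collapse = ", "))
  }
  fun <- switch(name, "simulate" = stage_simulate, "rtop" = stage_rtop,
                "parcel-stats" = stage_parcel_stats,
                "gradients" = stage_gradients,
                "connectivity" = stage_connectivity, "cca" = stage_cca)
  invisible(fun(config))
}

#' Run the full synthetic pipeline
#'
#' Executes all stages in order and writes `report.json` summarizing how
#' well each analysis recovered its planted ground truth: voxelwise RTOP
#' error, gradient direction error and Rayleigh significance, differential
#' mask Dice overlaps, stability sample sizes, and CCA recovery (in-sample
#' and leave-one-out).
#'
#' @param config a [pipeline_config()].
#' @return the report list, invisibly.
#' @export
run_all <- function(config = pipeline_config()) {
  run_stage("simulate", config)
  rtop <- run_stage("rtop", config)
  parcel <- run_stage("parcel-stats", config)
  grad <- run_stage("gradients", config)
  conn <- run_stage("connectivity", config)
  cca <- run_stage("cca", config)
  report <- list(
    rtop_median_rel_error = rtop$median_rel_error,
    rtop_max_rel_error = rtop$max_rel_error,
    anova = parcel$anova,
    min_stable_n = parcel$min_stable_n,
    direction_error_deg = list(left = grad$left$direction_error_deg,
                               right = grad$right$direction_error_deg),
    rayleigh_p = list(left = grad$left$rayleigh_p,
                      right = grad$right$rayleigh_p),
    connectivity_dice = conn$dice,
    cca_first_canonical_r = cca$canonical_correlations[1],
    planted_canonical_r = config$planted_canonical_r,
    loo_r = cca$loo_r)
  write_results_json(report, file.path(config$out_dir, "report.json"))
  manifest_add(config$out_dir, "report",
               file.path(config$out_dir, "report.json"))
  invisible(report)
}
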