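#' Pipeline configuration
#'
#' Bundles every tunable of the simulate -> GLM -> decode -> group -> ROI
#' chain into one serialisable object; a run is reproducible from
#' (config, seed) alone.
#'
#' @param grid_shape,voxel_size_mm simulated grid geometry.
#' @param n_subjects simulated participants.
#' @param runs_per_session,volumes_per_run,tr design overrides.
#' @param sigma,ar1,drift_amplitude noise parameters.
#' @param regions,amplitudes ground-truth region specs (see
#'   [ground_truth_config()]). In YAML, regions are given as
#'   `name: {center: [i, j, k], radius: r}`.
#' @param searchlight_radius,min_voxels searchlight geometry (voxels).
#' @param alpha,q,cluster_k,voxel_p,t_threshold,n_permutations,connectivity
#'   group-inference options.
#' @param smooth_fwhm_mm univariate smoothing kernel.
#' @param roi_radius_voxels ROI sphere radius; 0 skips the ROI stage.
#' @param tasks names of searchlight tasks to run (subset of
#'   `modality_s1`, `modality_s2`, `emotion_all`, `emotion_visual`,
#'   `emotion_voice`, `crossmodal`).
#' @param seed default master seed.
#' @param out_dir default output directory.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(grid_shape = c(12, 12, 12), voxel_size_mm = 8,
                            n_subjects = 4, runs_per_session = 6,
                            volumes_per_run = 160, tr = 3,
                            sigma = 1, ar1 = 0.3, drift_amplitude = 1,
                            regions = list(), amplitudes = NULL,
                            searchlight_radius = 5, min_voxels = 10,
                            alpha = 0.05, q = 0.05, cluster_k = 25,
                            voxel_p = 0.001, t_threshold = 3.9,
                            n_permutations = 100, connectivity = 26,
                            smooth_fwhm_mm = 6, roi_radius_voxels = 5,
                            tasks = c("modality_s1", "modality_s2",
                                      "emotion_all"),
                            seed = 1, out_dir = NULL) {
  region_specs <- lapply(regions, function(r) {
    if (inherits(r, "region_spec") || is.numeric(r)) r
    else region_sphere(unlist(r$center), r$radius)
  })
  structure(list(
    grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
    n_subjects = n_subjects, runs_per_session = runs_per_session,
    volumes_per_run = volumes_per_run, tr = tr,
    sigma = sigma, ar1 = ar1, drift_amplitude = drift_amplitude,
    regions = region_specs, amplitudes = amplitudes,
    searchlight_radius = searchlight_radius, min_voxels = min_voxels,
    alpha = alpha, q = q, cluster_k = cluster_k, voxel_p = voxel_p,
    t_threshold = t_threshold, n_permutations = n_permutations,
    connectivity = connectivity, smooth_fwhm_mm = smooth_fwhm_mm,
    roi_radius_voxels = roi_radius_voxels, tasks = tasks,
    seed = seed, out_dir = out_dir
  ), class = "pipeline_config")
}

pipeline_tasks <- function(names) {
  all <- list(
    modality_s1 = task_modality(1), modality_s2 = task_modality(2),
    modality = task_modality(), emotion_all = task_emotion_all(),
    emotion_visual = task_emotion_within(c("face", "body")),
    emotion_voice = task_emotion_within("voice")
  )
  out <- list()
  for (nm in names) {
    if (nm == "crossmodal") {
      cm <- crossmodal_task_set()
      names(cm) <- vapply(cm, `[[`, "", "name")
      out <- c(out, cm)
    } else if (nm %in% names(all)) {
      out[[nm]] <- all[[nm]]
    } else {
      stop("unknown task name in config: ", nm, call. = FALSE)
    }
  }
  out
}

manifest_entry <- function(path, stage, seed = NA) {
  data.frame(stage = stage, file = path,
             md5 = unname(tools::md5sum(path)), seed = seed)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> GLM -> searchlight decoding -> group inference -> ROI
#' analysis, writing every output under `out_dir` together with a manifest
#' (file, md5, stage, seeds, skipped stages). Identical (config, seed) pairs
#' produce hash-identical manifests.
#'
#' @param config a [pipeline_config()].
#' @param seed master seed (default: the config's).
#' @param out_dir output directory (default: the config's).
#' @param stages subset of `c("simulate", "glm", "decode", "group", "roi")`;
#'   later stages silently require earlier ones in the same call.
#' @return list with the in-memory results and the manifest data frame.
#' @export
run_pipeline <- function(config, seed = config$seed,
                         out_dir = config$out_dir,
                         stages = c("simulate", "glm", "decode", "group",
                                    "roi")) {
  stopifnot(inherits(config, "pipeline_config"), !is.null(out_dir))
  stages <- match.arg(stages, several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list()
  result <- list()

  design <- experiment_design(runs_per_session = config$runs_per_session,
                              volumes_per_run = config$volumes_per_run,
                              tr = config$tr)
  truth_cfg <- ground_truth_config(config$grid_shape, config$voxel_size_mm,
                                   regions = config$regions,
                                   amplitudes = config$amplitudes)
  sc <- sim_config(design, truth_cfg,
                   noise_model(config$sigma, config$ar1,
                               config$drift_amplitude),
                   n_subjects = config$n_subjects)

  dataset <- NULL
  if ("simulate" %in% stages) {
    dataset <- run_stage("simulate", generate_dataset(sc, seed, out_dir))
    for (f in dataset$files) {
      manifest[[length(manifest) + 1]] <- manifest_entry(f, "simulate", seed)
    }
    result$dataset <- dataset
  }

  betas_list <- NULL
  if ("glm" %in% stages) {
    if (is.null(dataset)) stop("stage 'glm' needs stage 'simulate'", call. = FALSE)
    betas_list <- run_stage("glm", lapply(dataset$subjects, function(runs) {
      estimate_trial_betas(runs, dataset$events)
    }))
    for (s in seq_along(betas_list)) {
      f <- file.path(out_dir, sprintf("sub-%02d_trial-betas.tsv", s))
      b <- betas_list[[s]]
      utils::write.table(cbind(b$labels, b$betas), f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      manifest[[length(manifest) + 1]] <- manifest_entry(f, "glm")
    }
    result$betas <- betas_list
  }

  maps_by_task <- NULL
  spec <- searchlight_spec(config$searchlight_radius, config$min_voxels)
  if ("decode" %in% stages) {
    if (is.null(betas_list)) stop("stage 'decode' needs stage 'glm'", call. = FALSE)
    tasks <- pipeline_tasks(config$tasks)
    sl <- searchlight_matrix(betas_list[[1]]$grid_shape,
                             betas_list[[1]]$brain_mask, spec)
    maps_by_task <- run_stage("decode", lapply(tasks, function(task) {
      lapply(betas_list, function(b) {
        if (task$kind == "crossmodal") crossmodal_decode(b, task, spec, sl)
        else searchlight_decode(b, task, spec, sl)
      })
    }))
    for (tn in names(maps_by_task)) {
      for (s in seq_along(maps_by_task[[tn]])) {
        m <- maps_by_task[[tn]][[s]]
        f <- file.path(out_dir, sprintf("sub-%02d_task-%s_accuracy.nii.gz",
                                        s, tn))
        vol <- array(NA_real_, m$grid_shape)
        vol[m$mask_idx] <- m$values
        write_nifti(vol, f, m$affine)
        sidecar <- sub("\\.nii\\.gz$", ".json", f)
        jsonlite::write_json(list(task = m$task, chance_level = m$chance_level,
                                  n_folds = m$n_folds,
                                  radius_voxels = spec$radius_voxels,
                                  min_voxels = spec$min_voxels,
                                  undefined_centers = sum(!m$defined)),
                             sidecar, auto_unbox = TRUE)
        manifest[[length(manifest) + 1]] <- manifest_entry(f, "decode")
        manifest[[length(manifest) + 1]] <- manifest_entry(sidecar, "decode")
      }
    }
    result$maps <- maps_by_task
  }

  if ("group" %in% stages) {
    if (is.null(maps_by_task)) stop("stage 'group' needs stage 'decode'", call. = FALSE)
    group <- run_stage("group", lapply(names(maps_by_task), function(tn) {
      gm <- ttest_vs_chance(maps_by_task[[tn]])
      fwe <- fwe_correct(gm, config$alpha)
      cl <- cluster_threshold(gm, config$voxel_p, config$cluster_k,
                              config$connectivity)
      f <- file.path(out_dir, sprintf("group_task-%s_clusters.tsv", tn))
      utils::write.table(cl$table, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      list(task = tn, stat = gm, fwe = fwe, clusters = cl, file = f)
    }))
    names(group) <- names(maps_by_task)
    for (g in group) {
      manifest[[length(manifest) + 1]] <- manifest_entry(g$file, "group")
    }
    result$group <- group
  }

  if ("roi" %in% stages && config$roi_radius_voxels > 0) {
    if (is.null(betas_list)) stop("stage 'roi' needs stage 'glm'", call. = FALSE)
    roi_res <- run_stage("roi", {
      tab <- roi_table()
      rois <- roi_masks(tab, config$grid_shape,
                        betas_list[[1]]$affine, config$roi_radius_voxels,
                        betas_list[[1]]$brain_mask)
      report <- roi_decode(betas_list, rois)
      f <- file.path(out_dir, "roi_decoding_report.tsv")
      utils::write.table(report, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      rdms <- lapply(rois, function(roi) {
        average_rdm(lapply(betas_list, function(b) {
          compute_rdm(condition_patterns(b, roi))
        }))
      })
      rfiles <- character(0)
      for (rn in names(rdms)) {
        rf <- file.path(out_dir, sprintf("roi-%s_rdm.tsv", gsub("\\W", "", rn)))
        utils::write.table(as.matrix(unclass(rdms[[rn]])), rf, sep = "\t",
                           quote = FALSE, row.names = TRUE, col.names = NA)
        rfiles <- c(rfiles, rf)
      }
      list(report = report, rdms = rdms, files = c(f, rfiles))
    })
    for (f in roi_res$files) {
      manifest[[length(manifest) + 1]] <- manifest_entry(f, "roi")
    }
    result$roi <- roi_res
  }

  manifest_df <- do.call(rbind, manifest)
  skipped <- setdiff(c("simulate", "glm", "decode", "group", "roi"), stages)
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(seed = seed, stages = stages, skipped = skipped,
                            files = manifest_df), mf, auto_unbox = TRUE,
                       digits = NA)
  result$manifest <- manifest_df
  result$manifest_file <- mf
  result
}
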