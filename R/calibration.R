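#' Construct an accuracy map from raw values
#'
#' Mainly for second-level work on externally computed (or directly simulated)
#' per-voxel accuracies.
#'
#' @param values per-voxel accuracy vector (NA = undefined).
#' @param grid_shape grid dimensions.
#' @param chance_level analytic chance probability.
#' @param mask_idx grid voxel index per value.
#' @param task task name tag.
#' @return an `accuracy_map`.
#' @export
accuracy_map <- function(values, grid_shape, chance_level,
                         mask_idx = seq_along(values), task = "custom") {
  structure(list(values = values, defined = !is.na(values), task = task,
                 chance_level = chance_level, n_folds = NA_integer_,
                 mask_idx = mask_idx, grid_shape = grid_shape,
                 spec = NULL, affine = grid_affine(grid_shape)),
            class = "accuracy_map")
}

#' Chance-level calibration on signal-free data
#'
#' Simulates a group with the full two-session schedule and all effect
#' amplitudes zero, estimates trial betas, and runs the four-class emotion
#' searchlight (all stimuli, leave-one-run-out) and the two-class modality
#' searchlight (per session pairing, averaged) for every subject. With no
#' signal, mean accuracy over defined voxels and subjects should sit at the
#' analytic chance levels (25% and 50%) within Monte-Carlo error.
#'
#' @param seed master seed.
#' @param n_subjects simulated participants.
#' @param grid_shape simulation grid.
#' @param sigma noise standard deviation.
#' @param radius_voxels searchlight radius.
#' @return list: `emotion` and `modality` each with the grand `mean`,
#'   per-subject means, the 95% CI half-width across subjects, `chance`, and
#'   `n_values` (defined voxels x subjects averaged).
#' @export
chance_calibration <- function(seed, n_subjects = 8,
                               grid_shape = c(12, 12, 12), sigma = 1,
                               radius_voxels = 5) {
  cfg <- sim_config(
    design = experiment_design(),
    truth = ground_truth_config(grid_shape = grid_shape),
    noise = noise_model(sigma = sigma),
    n_subjects = n_subjects
  )
  ds <- generate_dataset(cfg, seed)
  spec <- searchlight_spec(radius_voxels = radius_voxels)
  sl <- searchlight_matrix(grid_shape, ds$truth$brain_mask, spec)
  emo_task <- task_emotion_all()
  mod_tasks <- list(task_modality(1), task_modality(2))
  emo_means <- numeric(n_subjects)
  mod_means <- numeric(n_subjects)
  n_def <- 0L
  for (s in seq_len(n_subjects)) {
    b <- estimate_trial_betas(ds$subjects[[s]], ds$events)
    ds$subjects[[s]] <- NA  # free the raw series
    emo_map <- searchlight_decode(b, emo_task, spec, sl = sl)
    emo_means[s] <- map_mean_accuracy(emo_map)
    mod_means[s] <- mean(vapply(mod_tasks, function(tk) {
      map_mean_accuracy(searchlight_decode(b, tk, spec, sl = sl))
    }, numeric(1)))
    n_def <- sum(emo_map$defined)
  }
  summarise <- function(x, chance) {
    list(mean = mean(x), per_subject = x, chance = chance,
         ci_halfwidth = stats::qt(0.975, n_subjects - 1) *
           stats::sd(x) / sqrt(n_subjects),
         n_values = n_def * n_subjects)
  }
  list(emotion = summarise(emo_means, 0.25),
       modality = summarise(mod_means, 0.5),
       n_subjects = n_subjects, grid_shape = grid_shape)
}

#' Ground-truth configurations for the dissociation experiment
#'
#' The modality-specific scenario plants independent per-emotion patterns for
#' faces, bodies and voices in three disjoint spheres (no pattern shared
#' across stimulus types anywhere); the supramodal scenario adds a fourth
#' sphere whose emotion patterns are identical across stimulus types. Region
#' amplitudes default to 6 over radius-2 spheres (33 voxels), i.e. a
#' per-voxel signal RMS of about one trial-beta noise standard deviation -- a
#' strong positive control.
#'
#' @param grid_shape simulation grid (centres assume at least 12 voxels per
#'   axis).
#' @param supramodal include the supramodal region.
#' @param amplitude region effect amplitude.
#' @return a [ground_truth_config()].
#' @export
dissociation_truth <- function(grid_shape = c(12, 12, 12), supramodal = FALSE,
                               amplitude = 6) {
  regions <- list(
    emotion_face_region = region_sphere(c(4, 4, 4), 2),
    emotion_body_region = region_sphere(c(9, 9, 4), 2),
    emotion_voice_region = region_sphere(c(4, 9, 9), 2)
  )
  if (supramodal) {
    regions$supramodal_emotion_region <- region_sphere(c(9, 4, 9), 2)
  }
  ground_truth_config(grid_shape = grid_shape, regions = regions,
                      amplitudes = stats::setNames(rep(amplitude,
                                                       length(regions)),
                                                   names(regions)))
}

#' Within-modality versus cross-modal dissociation experiment
#'
#' Simulates a group under a chosen ground truth, decodes emotion within the
#' voice modality (leave-one-run-out searchlight) and across modalities (all
#' four cross-modal directions), and returns the group statistics needed to
#' ask the central question: is emotion decodable within a modality while no
#' voxel generalises across modalities -- and does planting a supramodal
#' region flip the cross-modal result inside it?
#'
#' @param seed master seed.
#' @param supramodal plant a supramodal emotion region.
#' @param n_subjects simulated participants.
#' @param grid_shape simulation grid.
#' @param amplitude region effect amplitude.
#' @param radius_voxels searchlight radius.
#' @return list with the ground `truth`, `within` (per-subject voice-emotion
#'   maps and their group map), and `crossmodal` (per direction: subject maps
#'   and group map).
#' @export
dissociation_experiment <- function(seed, supramodal = FALSE, n_subjects = 8,
                                    grid_shape = c(12, 12, 12), amplitude = 6,
                                    radius_voxels = 5) {
  cfg <- sim_config(
    design = experiment_design(),
    truth = dissociation_truth(grid_shape, supramodal, amplitude),
    noise = noise_model(sigma = 1),
    n_subjects = n_subjects
  )
  ds <- generate_dataset(cfg, seed)
  spec <- searchlight_spec(radius_voxels = radius_voxels)
  sl <- searchlight_matrix(grid_shape, ds$truth$brain_mask, spec)
  betas <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    betas[[s]] <- estimate_trial_betas(ds$subjects[[s]], ds$events)
    ds$subjects[[s]] <- NA
  }
  voice_task <- task_emotion_within("voice")
  within_maps <- lapply(betas, searchlight_decode, task = voice_task,
                        spec = spec, sl = sl)
  cm_tasks <- crossmodal_task_set()
  crossmodal <- lapply(cm_tasks, function(task) {
    maps <- lapply(betas, crossmodal_decode, task = task, spec = spec, sl = sl)
    list(task = task$name, maps = maps, group = ttest_vs_chance(maps))
  })
  names(crossmodal) <- vapply(cm_tasks, `[[`, "", "name")
  list(truth = ds$truth,
       within = list(task = voice_task$name, maps = within_maps,
                     group = ttest_vs_chance(within_maps)),
       crossmodal = crossmodal,
       betas = betas)
}
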