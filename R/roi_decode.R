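#' The ten decoding tasks of the ROI report
#'
#' Mirrors the ROI decoding table: modality (reported as the average of body
#' vs voice in session 1 and face vs voice in session 2), emotion from all
#' stimuli, emotion within body / face / voice session 1 / voice session 2,
#' and the four cross-modal directions.
#'
#' @param emotions ordered emotion labels.
#' @return named list of `decoding_task`s (the modality entry is a list of the
#'   two per-session tasks whose accuracies are averaged).
#' @export
roi_default_tasks <- function(emotions = c("anger", "happy", "neutral", "fear")) {
  list(
    modality = list(task_modality(1), task_modality(2)),
    emotion_all = task_emotion_all(emotions),
    emotion_body = task_emotion_within("body", emotions = emotions),
    emotion_face = task_emotion_within("face", emotions = emotions),
    emotion_voice_s1 = task_emotion_within("voice", session = 1,
                                           emotions = emotions),
    emotion_voice_s2 = task_emotion_within("voice", session = 2,
                                           emotions = emotions),
    emotion_body_to_voice = task_emotion_crossmodal("body", "voice", emotions),
    emotion_voice_to_body = task_emotion_crossmodal("voice", "body", emotions),
    emotion_face_to_voice = task_emotion_crossmodal("face", "voice", emotions),
    emotion_voice_to_face = task_emotion_crossmodal("voice", "face", emotions)
  )
}

roi_task_accuracy <- function(X, labels, task) {
  if (task$kind == "crossmodal") {
    tr_idx <- which(task$train_filter(labels))
    te_idx <- which(task$test_filter(labels))
    model <- gnb_fit(X[tr_idx, , drop = FALSE],
                     factor(task$label_fun(labels[tr_idx, , drop = FALSE]),
                            levels = task$levels))
    pred <- gnb_predict(model, X[te_idx, , drop = FALSE])$class
    return(accuracy(pred, task$label_fun(labels[te_idx, , drop = FALSE])))
  }
  keep <- which(task$filter(labels))
  y <- factor(task$label_fun(labels[keep, , drop = FALSE]), levels = task$levels)
  runs <- labels$run[keep]
  Xk <- X[keep, , drop = FALSE]
  folds <- leave_one_run_out_folds(runs)
  mean(vapply(folds, function(f) {
    model <- gnb_fit(Xk[f$train, , drop = FALSE], y[f$train])
    accuracy(gnb_predict(model, Xk[f$test, , drop = FALSE])$class,
             as.character(y[f$test]))
  }, numeric(1)))
}

#' ROI decoding report
#'
#' Decodes each task from all of an ROI's voxels at once (no searchlight):
#' Gaussian Naive Bayes with leave-one-run-out cross-validation (single split
#' for cross-modal tasks) per subject, a one-sample t-test of the subject
#' accuracies against chance per ROI x task cell, and Benjamini-Hochberg FDR
#' correction across the full ROI x task grid.
#'
#' @param betas_list per-subject `trial_beta_set`s.
#' @param rois named list of grid voxel index vectors (e.g. [roi_masks()]).
#' @param tasks task list as from [roi_default_tasks()].
#' @param q FDR level.
#' @return an `roi_decoding_report` data frame: one row per ROI x task with
#'   mean accuracy, chance level, t, df, uncorrected one-sided p and FDR
#'   adjusted p.
#' @export
roi_decode <- function(betas_list, rois, tasks = roi_default_tasks(),
                       q = 0.05) {
  stopifnot(length(betas_list) >= 2, length(rois) >= 1)
  mask_idx <- which(betas_list[[1]]$brain_mask)
  rows <- list()
  for (rn in names(rois)) {
    cols <- match(rois[[rn]], mask_idx)
    if (anyNA(cols)) stop("ROI '", rn, "' has voxels outside the beta mask",
                          call. = FALSE)
    for (tn in names(tasks)) {
      task <- tasks[[tn]]
      parts <- if (inherits(task, "decoding_task")) list(task) else task
      acc <- vapply(betas_list, function(b) {
        mean(vapply(parts, function(tk) {
          roi_task_accuracy(b$betas[, cols, drop = FALSE], b$labels, tk)
        }, numeric(1)))
      }, numeric(1))
      chance <- parts[[1]]$chance_level
      n <- length(acc)
      mu <- mean(acc) - chance
      sd <- stats::sd(acc)
      tv <- if (sd == 0 && mu == 0) 0 else mu / (sd / sqrt(n))
      pv <- if (sd == 0 && mu > 0) 0 else stats::pt(tv, n - 1, lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        roi = rn, task = tn, accuracy = mean(acc), chance = chance,
        t = tv, df = n - 1, p = pv)
    }
  }
  rep <- do.call(rbind, rows)
  fdr <- bh_fdr(rep$p, q)
  rep$p_fdr <- fdr$p_adjusted
  rep$significant <- fdr$reject
  attr(rep, "fdr_scope") <- "whole table"
  class(rep) <- c("roi_decoding_report", "data.frame")
  rep
}
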