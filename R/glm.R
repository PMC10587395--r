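new_design_matrix <- function(values, interest, labels = NULL) {
  stopifnot(is.matrix(values), length(interest) == ncol(values))
  zero <- interest & colSums(abs(values)) == 0
  if (any(zero)) {
    stop("all-zero regressor(s) of interest: ",
         paste(colnames(values)[zero], collapse = ", "), call. = FALSE)
  }
  structure(list(values = values, interest = interest, labels = labels),
            class = "design_matrix")
}

nuisance_block <- function(n_volumes, tr, motion, drift_cutoff) {
  cols <- list()
  if (!is.null(motion) && ncol(as.matrix(motion)) > 0) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_volumes) {
      stop("motion regressors must have one row per volume", call. = FALSE)
    }
    colnames(motion) <- paste0("motion_", seq_len(ncol(motion)))
    cols$motion <- motion
  }
  if (!is.null(drift_cutoff)) {
    D <- cosine_drift(n_volumes, tr, drift_cutoff)
    if (ncol(D)) cols$drift <- D
  }
  cols$constant <- matrix(1, n_volumes, 1, dimnames = list(NULL, "constant"))
  do.call(cbind, cols)
}

#' Trial-wise design matrix for one run
#'
#' One regressor of interest per non-catch trial (the 1 s boxcar convolved
#' with the canonical HRF, sampled at volume times), fitted jointly in a
#' single least-squares-all model, plus nuisance regressors: a pooled catch
#' regressor, optional motion series, the cosine drift set, and a constant.
#'
#' @param events one run's event rows.
#' @param n_volumes,tr run geometry.
#' @param hrf an [hrf_spec()].
#' @param motion optional volumes x k matrix of motion nuisance series.
#' @param drift_cutoff high-pass cutoff in seconds (`NULL` drops the drift set).
#' @param dt fine convolution grid step, seconds.
#' @return a `design_matrix`; `$labels` aligns one row per interest regressor
#'   with the trial's labels.
#' @export
build_trialwise_design <- function(events, n_volumes, tr, hrf = hrf_spec(),
                                   motion = NULL, drift_cutoff = 128,
                                   dt = 0.1) {
  live <- events[!events$is_catch, , drop = FALSE]
  if (nrow(live) == 0) stop("no non-catch trials in events", call. = FALSE)
  if (anyDuplicated(live$onset)) {
    stop("design-degenerate: trials with identical onsets", call. = FALSE)
  }
  X <- trial_regressor_matrix(live$onset, live$duration, n_volumes, tr, hrf, dt)
  colnames(X) <- sprintf("trial_%03d", seq_len(ncol(X)))
  nuis <- list()
  catch <- events[events$is_catch, , drop = FALSE]
  if (nrow(catch)) {
    xc <- trial_regressor_matrix(catch$onset, catch$duration, n_volumes, tr,
                                 hrf, dt)
    nuis$catch <- matrix(rowSums(xc), ncol = 1, dimnames = list(NULL, "catch"))
  }
  nb <- nuisance_block(n_volumes, tr, motion, drift_cutoff)
  values <- do.call(cbind, c(list(X), nuis, list(nb)))
  interest <- c(rep(TRUE, ncol(X)), rep(FALSE, ncol(values) - ncol(X)))
  lab_cols <- intersect(c("stimulus_type", "emotion", "session", "run",
                          "run_half", "actor", "onset"), names(live))
  new_design_matrix(values, interest, live[, lab_cols, drop = FALSE])
}

#' Condition design matrix for one run
#'
#' One regressor of interest per (stimulus type, emotion) condition present in
#' the run (12 when all three categories appear), plus nuisance regressors:
#' a block-start regressor (an event at the first onset of each run half), a
#' pooled catch regressor, six motion series (generated as smooth random walks
#' when not supplied), cosine drift, and a constant. Conditions expected by the
#' design but absent from the run are recorded in the `missing_conditions`
#' attribute rather than entered as zero columns.
#'
#' @inheritParams build_trialwise_design
#' @param expected_conditions character vector of condition names that should
#'   exist (`NULL` derives the full stimulus-type x emotion crossing from the
#'   events present).
#' @param emotions,stimulus_types label sets defining the full crossing.
#' @return a `design_matrix`; `$labels` has one row per condition regressor.
#' @export
build_condition_design <- function(events, n_volumes, tr, hrf = hrf_spec(),
                                   motion = NULL, drift_cutoff = 128, dt = 0.1,
                                   emotions = c("anger", "happy", "neutral", "fear"),
                                   stimulus_types = c("face", "body", "voice")) {
  live <- events[!events$is_catch, , drop = FALSE]
  if (nrow(live) == 0) stop("no non-catch trials in events", call. = FALSE)
  full <- expand.grid(stimulus_type = stimulus_types, emotion = emotions,
                      stringsAsFactors = FALSE)
  full$condition <- paste(full$stimulus_type, full$emotion, sep = "_")
  live$condition <- paste(live$stimulus_type, live$emotion, sep = "_")
  present <- full[full$condition %in% live$condition, , drop = FALSE]
  missing <- setdiff(full$condition, present$condition)
  X <- vapply(present$condition, function(cn) {
    tr_rows <- live[live$condition == cn, , drop = FALSE]
    rowSums(trial_regressor_matrix(tr_rows$onset, tr_rows$duration,
                                   n_volumes, tr, hrf, dt))
  }, numeric(n_volumes))
  colnames(X) <- present$condition
  nuis <- list()
  starts <- vapply(split(live$onset, paste(live$run, live$run_half)), min,
                   numeric(1))
  nuis$block_start <- matrix(
    rowSums(trial_regressor_matrix(starts, rep(1, length(starts)),
                                   n_volumes, tr, hrf, dt)),
    ncol = 1, dimnames = list(NULL, "block_start"))
  catch <- events[events$is_catch, , drop = FALSE]
  if (nrow(catch)) {
    xc <- trial_regressor_matrix(catch$onset, catch$duration, n_volumes, tr,
                                 hrf, dt)
    nuis$catch <- matrix(rowSums(xc), ncol = 1, dimnames = list(NULL, "catch"))
  }
  if (is.null(motion)) motion <- synthetic_motion(n_volumes)
  nb <- nuisance_block(n_volumes, tr, motion, drift_cutoff)
  values <- do.call(cbind, c(list(X), nuis, list(nb)))
  interest <- c(rep(TRUE, ncol(X)), rep(FALSE, ncol(values) - ncol(X)))
  dm <- new_design_matrix(values, interest,
                          present[, c("stimulus_type", "emotion"), drop = FALSE])
  attr(dm, "missing_conditions") <- missing
  dm
}

#' Smooth random-walk motion nuisance series
#'
#' Six slowly varying series standing in for realignment parameters when the
#' simulation provides none (simulated data contain no motion; the columns are
#' exercised as nuisance regressors only).
#'
#' @param n_volumes series length.
#' @param n number of series.
#' @param sd innovation standard deviation.
#' @return `n_volumes` x `n` matrix.
#' @export
synthetic_motion <- function(n_volumes, n = 6, sd = 0.02) {
  M <- apply(matrix(stats::rnorm(n_volumes * n, sd = sd), n_volumes, n), 2,
             cumsum)
  scale(M, center = TRUE, scale = FALSE)
}

#' Estimate response amplitudes by ordinary least squares
#'
#' Fits the design to every voxel's time series in one QR decomposition and
#' returns the interest-regressor coefficients.
#'
#' @param run a `bold_run` (or a plain volumes x voxels matrix).
#' @param design a `design_matrix` with matching row count.
#' @return a `trial_beta_set`: `betas` (interest regressors x voxels, stored
#'   trials-by-voxels), `labels` aligned row-wise, and the grid geometry when
#'   a `bold_run` was supplied.
#' @export
estimate_betas <- function(run, design) {
  Y <- if (inherits(run, "bold_run")) run$data else as.matrix(run)
  X <- design$values
  if (nrow(X) != nrow(Y)) {
    stop("design rows must match run volumes", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  B <- qr.coef(qrX, Y)
  betas <- B[design$interest, , drop = FALSE]
  rownames(betas) <- colnames(X)[design$interest]
  out <- list(betas = betas, labels = design$labels)
  if (inherits(run, "bold_run")) {
    out$grid_shape <- run$grid_shape
    out$brain_mask <- run$brain_mask
    out$affine <- run$affine
    out$voxel_size_mm <- run$voxel_size_mm
  }
  structure(out, class = "trial_beta_set")
}

#' Trial-wise betas for a whole subject
#'
#' Builds one least-squares-all model per run and stacks the interest betas
#' into a single trials x voxels matrix with aligned labels.
#'
#' @param runs list of `bold_run`s (one per run).
#' @param events the full event table covering those runs.
#' @param hrf,motion,drift_cutoff,dt passed to [build_trialwise_design()].
#' @return a `trial_beta_set` spanning all runs.
#' @export
estimate_trial_betas <- function(runs, events, hrf = hrf_spec(), motion = NULL,
                                 drift_cutoff = 128, dt = 0.1) {
  run_ids <- sort(unique(events$run))
  stopifnot(length(runs) == length(run_ids))
  pieces <- lapply(seq_along(run_ids), function(i) {
    ev <- events[events$run == run_ids[i], , drop = FALSE]
    dm <- build_trialwise_design(ev, nrow(runs[[i]]$data), runs[[i]]$tr,
                                 hrf = hrf, motion = motion,
                                 drift_cutoff = drift_cutoff, dt = dt)
    estimate_betas(runs[[i]], dm)
  })
  out <- pieces[[1]]
  out$betas <- do.call(rbind, lapply(pieces, `[[`, "betas"))
  out$labels <- do.call(rbind, lapply(pieces, `[[`, "labels"))
  rownames(out$betas) <- NULL
  rownames(out$labels) <- NULL
  out
}

#' Condition-wise betas for a whole subject
#'
#' Fits the condition GLM run by run (optionally on spatially smoothed data)
#' and averages each condition's beta across the runs in which it occurs.
#'
#' @param runs list of `bold_run`s.
#' @param events full event table.
#' @param smooth_fwhm_mm Gaussian smoothing FWHM applied to each volume before
#'   fitting (0 disables; the univariate path uses 6 mm).
#' @param hrf,motion,drift_cutoff,dt passed to [build_condition_design()].
#' @return a `condition_beta_set`: `betas` (conditions x voxels) and `labels`
#'   (stimulus_type, emotion per row).
#' @export
estimate_condition_betas <- function(runs, events, smooth_fwhm_mm = 0,
                                     hrf = hrf_spec(), motion = NULL,
                                     drift_cutoff = 128, dt = 0.1) {
  run_ids <- sort(unique(events$run))
  stopifnot(length(runs) == length(run_ids))
  acc <- NULL; cnt <- NULL; labels <- NULL
  for (i in seq_along(run_ids)) {
    ev <- events[events$run == run_ids[i], , drop = FALSE]
    run <- runs[[i]]
    if (smooth_fwhm_mm > 0) run <- smooth_bold_run(run, smooth_fwhm_mm)
    dm <- build_condition_design(ev, nrow(run$data), run$tr, hrf = hrf,
                                 motion = motion, drift_cutoff = drift_cutoff,
                                 dt = dt,
                                 emotions = unique(stats::na.omit(events$emotion)),
                                 stimulus_types = unique(events$stimulus_type))
    bs <- estimate_betas(run, dm)
    if (is.null(acc)) {
      full <- expand.grid(stimulus_type = unique(events$stimulus_type),
                          emotion = unique(stats::na.omit(events$emotion)),
                          stringsAsFactors = FALSE)
      labels <- full
      acc <- matrix(0, nrow(full), ncol(bs$betas),
                    dimnames = list(paste(full$stimulus_type, full$emotion,
                                          sep = "_"), NULL))
      cnt <- numeric(nrow(full))
    }
    rows <- match(rownames(bs$betas), rownames(acc))
    acc[rows, ] <- acc[rows, , drop = FALSE] + bs$betas
    cnt[rows] <- cnt[rows] + 1
  }
  if (any(cnt == 0)) {
    stop("condition(s) absent from every run: ",
         paste(rownames(acc)[cnt == 0], collapse = ", "), call. = FALSE)
  }
  structure(list(betas = acc / cnt, labels = labels,
                 grid_shape = runs[[1]]$grid_shape,
                 brain_mask = runs[[1]]$brain_mask,
                 affine = runs[[1]]$affine),
            class = "condition_beta_set")
}
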