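#' Noise model for simulated BOLD series
#'
#' Stationary AR(1) Gaussian noise (marginal standard deviation `sigma`,
#' lag-1 autocorrelation `ar1`) plus a smooth low-frequency drift built from
#' the cosine basis with independent Gaussian coefficients of standard
#' deviation `drift_amplitude`.
#'
#' @param sigma noise standard deviation in signal units (>= 0).
#' @param ar1 lag-1 autocorrelation in \[0, 1).
#' @param drift_amplitude drift coefficient scale in signal units (>= 0).
#' @return a `noise_model` list.
#' @export
noise_model <- function(sigma = 1, ar1 = 0.3, drift_amplitude = 1) {
  if (sigma < 0 || drift_amplitude < 0) {
    stop("sigma and drift_amplitude must be non-negative", call. = FALSE)
  }
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must be in [0, 1)", call. = FALSE)
  structure(list(sigma = sigma, ar1 = ar1, drift_amplitude = drift_amplitude),
            class = "noise_model")
}

new_bold_run <- function(data, truth, tr, run, session) {
  structure(list(data = data, grid_shape = truth$grid_shape,
                 brain_mask = truth$brain_mask, affine = truth$affine,
                 voxel_size_mm = truth$voxel_size_mm, tr = tr,
                 run = run, session = session),
            class = "bold_run")
}

#' Simulate one run's voxel time series
#'
#' Voxel series = sum over non-catch trials of (ground-truth condition
#' amplitude x HRF-convolved 1 s boxcar) + stationary AR(1) Gaussian noise +
#' cosine drift with random coefficients. Deterministic under `seed`.
#'
#' @param events the run's event rows (one run only).
#' @param truth a `ground_truth` from [simulate_patterns()].
#' @param noise a [noise_model()].
#' @param design the [experiment_design()] (supplies volumes and TR).
#' @param seed integer seed for this run's noise.
#' @param hrf an [hrf_spec()].
#' @param dt fine time grid step for convolution, seconds.
#' @return a `bold_run`: `data` is a volumes x masked-voxels matrix.
#' @export
simulate_run <- function(events, truth, noise, design, seed,
                         hrf = hrf_spec(), dt = 0.1) {
  if (length(unique(events$run)) != 1) {
    stop("simulate_run expects the events of exactly one run", call. = FALSE)
  }
  set.seed(seed)
  nv <- design$volumes_per_run
  live <- events[!events$is_catch, , drop = FALSE]
  X <- trial_regressor_matrix(live$onset, live$duration, nv, design$tr, hrf, dt)
  A <- trial_amplitudes(truth, live)
  sig <- X %*% A
  V <- ncol(A)
  if (noise$sigma > 0) {
    innov_sd <- noise$sigma * sqrt(1 - noise$ar1^2)
    E <- matrix(stats::rnorm(nv * V, sd = innov_sd), nv, V)
    E[1, ] <- stats::rnorm(V, sd = noise$sigma)  # stationary start
    if (noise$ar1 > 0) {
      for (t in 2:nv) E[t, ] <- noise$ar1 * E[t - 1, ] + E[t, ]
    }
    sig <- sig + E
  }
  if (noise$drift_amplitude > 0) {
    C <- cosine_drift(nv, design$tr)
    if (ncol(C)) {
      B <- matrix(stats::rnorm(ncol(C) * V, sd = noise$drift_amplitude),
                  ncol(C), V)
      sig <- sig + C %*% B
    }
  }
  new_bold_run(sig, truth, design$tr, unique(events$run),
               unique(events$session))
}

#' Simulation configuration
#'
#' @param design an [experiment_design()].
#' @param truth a [ground_truth_config()].
#' @param noise a [noise_model()].
#' @param n_subjects number of simulated participants (>= 2; the group stages
#'   need at least two).
#' @param hrf an [hrf_spec()] shared by simulation and estimation.
#' @return a `sim_config` list.
#' @export
sim_config <- function(design = experiment_design(),
                       truth = ground_truth_config(),
                       noise = noise_model(),
                       n_subjects = 13L,
                       hrf = hrf_spec()) {
  if (n_subjects < 2) stop("n_subjects must be at least 2", call. = FALSE)
  structure(list(design = design, truth = truth, noise = noise,
                 n_subjects = as.integer(n_subjects), hrf = hrf),
            class = "sim_config")
}

#' Generate a full multi-subject dataset
#'
#' All subjects share one schedule and one set of ground-truth regions and
#' patterns (the group effect), but receive independent noise. With an output
#' directory the runs are written as NIfTI, the schedule as a BIDS-style
#' events TSV, and the ground truth as a JSON sidecar.
#'
#' @param config a [sim_config()].
#' @param seed master seed; stage seeds are derived with [derive_seeds()].
#' @param out_dir optional output directory.
#' @return list with `events`, `truth`, `subjects` (each a list of `bold_run`s)
#'   and, when written, `files`.
#' @export
generate_dataset <- function(config, seed, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_runs <- config$design$n_sessions * config$design$runs_per_session
  seeds <- derive_seeds(seed, 2 + config$n_subjects * n_runs)
  events <- build_design(config$design, seeds[1])
  truth <- simulate_patterns(config$truth, seeds[2],
                             emotions = config$design$emotions,
                             stimulus_types = config$design$stimulus_types)
  subjects <- vector("list", config$n_subjects)
  files <- list()
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  for (s in seq_len(config$n_subjects)) {
    runs <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      run_seed <- seeds[2 + (s - 1) * n_runs + r]
      runs[[r]] <- simulate_run(events[events$run == r, , drop = FALSE],
                                truth, config$noise, config$design, run_seed,
                                hrf = config$hrf)
      if (!is.null(out_dir)) {
        f <- file.path(out_dir, sprintf("sub-%02d_run-%02d_bold.nii.gz", s, r))
        write_bold_run(runs[[r]], f)
        files <- c(files, f)
      }
    }
    subjects[[s]] <- runs
  }
  if (!is.null(out_dir)) {
    fe <- file.path(out_dir, "events.tsv")
    write_events(events, fe)
    ft <- file.path(out_dir, "ground_truth.json")
    write_ground_truth(truth, ft)
    files <- c(files, fe, ft)
  }
  list(events = events, truth = truth, subjects = subjects,
       files = unlist(files), seed = seed)
}
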