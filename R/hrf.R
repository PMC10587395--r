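#' Canonical double-gamma HRF parameters
#'
#' The widely used difference-of-gamma-densities parameterisation: a positive
#' response gamma peaking around 5 s and an undershoot gamma peaking around
#' 15 s, subtracted at 1/6 amplitude.
#'
#' @param peak_delay,undershoot_delay gamma delays in seconds (mean = delay
#'   when dispersion is 1).
#' @param peak_dispersion,undershoot_dispersion gamma scale parameters.
#' @param peak_undershoot_ratio positive-to-undershoot amplitude ratio.
#' @param kernel_length kernel support in seconds.
#' @return an `hrf_spec` list.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_dispersion = 1, undershoot_dispersion = 1,
                     peak_undershoot_ratio = 6, kernel_length = 32) {
  if (peak_dispersion <= 0 || undershoot_dispersion <= 0) {
    stop("HRF dispersions must be positive", call. = FALSE)
  }
  stopifnot(peak_delay > 0, undershoot_delay > 0, peak_undershoot_ratio > 0,
            kernel_length > 0)
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 peak_undershoot_ratio = peak_undershoot_ratio,
                 kernel_length = kernel_length),
            class = "hrf_spec")
}

#' Sample the canonical HRF kernel
#'
#' Difference of two gamma densities (shape = delay / dispersion,
#' scale = dispersion) sampled every `tr` seconds starting at 0; the number of
#' samples is `ceiling(kernel_length / tr)` and the peak is normalised to 1.
#'
#' @param spec an [hrf_spec()].
#' @param tr sampling interval in seconds (the TR for volume-rate kernels, or
#'   a finer step for design construction).
#' @return numeric kernel vector with peak 1.
#' @export
canonical_hrf <- function(spec = hrf_spec(), tr) {
  stopifnot(inherits(spec, "hrf_spec"), tr > 0)
  t <- seq(0, by = tr, length.out = ceiling(spec$kernel_length / tr))
  h <- stats::dgamma(t, shape = spec$peak_delay / spec$peak_dispersion,
                     scale = spec$peak_dispersion) -
    stats::dgamma(t, shape = spec$undershoot_delay / spec$undershoot_dispersion,
                  scale = spec$undershoot_dispersion) / spec$peak_undershoot_ratio
  h / max(h)
}

#' Cosine drift basis (discrete cosine set)
#'
#' Low-frequency drift regressors equivalent to high-pass filtering at the
#' given cutoff: components k = 1 .. floor(2 T / cutoff) of the DCT-II basis
#' (the constant term is excluded; add an intercept separately).
#'
#' @param n_volumes number of time points.
#' @param tr repetition time in seconds.
#' @param cutoff high-pass cutoff period in seconds.
#' @return matrix with `n_volumes` rows and one column per retained component
#'   (possibly zero columns).
#' @export
cosine_drift <- function(n_volumes, tr, cutoff = 128) {
  stopifnot(n_volumes >= 1, tr > 0, cutoff > 0)
  n_basis <- max(0L, floor(2 * n_volumes * tr / cutoff))
  tt <- seq_len(n_volumes) - 0.5
  C <- vapply(seq_len(n_basis),
              function(k) cos(pi * k * tt / n_volumes),
              numeric(n_volumes))
  matrix(C, nrow = n_volumes, ncol = n_basis,
         dimnames = list(NULL, if (n_basis) paste0("drift_", seq_len(n_basis))))
}

#' HRF-convolved regressors for a set of events
#'
#' Builds each event's boxcar (duration in seconds) on a fine time grid,
#' convolves it with the canonical HRF sampled on that grid, and reads the
#' result off at volume acquisition times `0, tr, 2 tr, ...`.
#'
#' @param onsets,durations event timing in seconds from run start.
#' @param n_volumes,tr run geometry.
#' @param hrf an [hrf_spec()].
#' @param dt fine grid step in seconds.
#' @return `n_volumes` x `length(onsets)` regressor matrix.
#' @export
trial_regressor_matrix <- function(onsets, durations, n_volumes, tr,
                                   hrf = hrf_spec(), dt = 0.1) {
  stopifnot(length(onsets) >= 1, tr > 0, dt > 0)
  durations <- rep_len(durations, length(onsets))
  run_len <- n_volumes * tr
  if (any(onsets < 0) || any(onsets + durations > run_len + 1e-9)) {
    stop("events extend outside the run", call. = FALSE)
  }
  L <- ceiling(run_len / dt)
  h <- canonical_hrf(hrf, dt)
  H <- cumsum(h)
  nh <- length(h)
  vol_idx <- round(seq(0, by = tr, length.out = n_volumes) / dt) + 1L
  X <- matrix(0, n_volumes, length(onsets))
  for (i in seq_along(onsets)) {
    a <- min(L, floor(onsets[i] / dt) + 1L)
    b <- min(L, ceiling((onsets[i] + durations[i]) / dt))
    len <- b - a + 1L
    # boxcar * HRF in closed form: a difference of the HRF's cumulative sum
    nn <- len + nh - 1L
    pos <- seq_len(nn)
    lo <- pos - len
    hb <- H[pmin(pos, nh)]
    started <- lo >= 1L
    hb[started] <- hb[started] - H[pmin(lo[started], nh)]
    rel <- vol_idx - a + 1L
    ok <- rel >= 1L & rel <= nn
    X[ok, i] <- hb[rel[ok]]
  }
  X
}
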