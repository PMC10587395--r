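EVENT_COLUMNS <- c("onset", "duration", "trial_type", "stimulus_type",
                   "emotion", "session", "run", "run_half", "actor", "is_catch")

#' Write / read an event table (BIDS-events dialect TSV)
#'
#' Tab-separated with the columns `onset`, `duration`, `trial_type`,
#' `stimulus_type`, `emotion`, `session`, `run`, `run_half`, `actor`,
#' `is_catch`; missing emotion (catch trials) is written as `n/a`.
#'
#' @param events an event table.
#' @param path file path.
#' @return `write_events` returns the path invisibly; `read_events` returns an
#'   `event_table` data frame, erroring on any missing required column.
#' @export
write_events <- function(events, path) {
  utils::write.table(events[, EVENT_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path, call. = FALSE)
  ev <- utils::read.delim(path, na.strings = "n/a", stringsAsFactors = FALSE)
  missing <- setdiff(EVENT_COLUMNS, names(ev))
  if (length(missing)) {
    stop("events file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ev$is_catch <- as.logical(ev$is_catch)
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Write / read a volume as NIfTI-1
#'
#' The affine is stored as the sform (code 2); voxel indices are 0-based in
#' the NIfTI convention, so this package's 1-based voxel (1,1,1) maps to the
#' affine's translation column.
#'
#' @param arr 3-D or 4-D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param affine 4 x 4 voxel-to-mm matrix (1-based convention as used
#'   throughout this package).
#' @param tr repetition time stored in the header for 4-D series.
#' @return `write_nifti` the path; `read_nifti` a list `(data, affine, tr)`.
#' @export
write_nifti <- function(arr, path, affine = NULL, tr = NULL) {
  img <- RNifti::asNifti(arr)
  if (!is.null(affine)) {
    # convert 1-based voxel->mm to NIfTI's 0-based convention
    aff0 <- affine
    aff0[1:3, 4] <- affine[1:3, 4] + affine[1:3, 1:3] %*% rep(1, 3)
    RNifti::sform(img) <- structure(aff0, code = 2L)
  }
  if (!is.null(tr)) RNifti::pixdim(img)[4] <- tr
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  aff0 <- RNifti::xform(img)
  aff <- matrix(as.numeric(aff0), 4, 4)
  aff[1:3, 4] <- aff[1:3, 4] - aff[1:3, 1:3] %*% rep(1, 3)
  list(data = array(as.numeric(img), dim(img)), affine = aff,
       tr = unname(RNifti::pixdim(img)[min(4, length(RNifti::pixdim(img)))]))
}

#' Write a simulated run as a 4-D NIfTI volume
#'
#' Masked voxels are placed back on the grid (off-mask voxels zero).
#'
#' @param run a `bold_run`.
#' @param path output path.
#' @return the path invisibly.
#' @export
write_bold_run <- function(run, path) {
  nv <- nrow(run$data)
  arr <- array(0, c(run$grid_shape, nv))
  mask_idx <- which(run$brain_mask)
  nvox_grid <- prod(run$grid_shape)
  for (t in seq_len(nv)) arr[(t - 1) * nvox_grid + mask_idx] <- run$data[t, ]
  write_nifti(arr, path, run$affine, run$tr)
}

#' Write / read a ground-truth JSON sidecar
#'
#' Stores grid geometry, region voxel lists, amplitudes and the seed (the
#' patterns themselves are reproducible from the seed).
#'
#' @param truth a `ground_truth`.
#' @param path file path.
#' @return `write_ground_truth` the path; `read_ground_truth` a list.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(
    grid_shape = truth$grid_shape, voxel_size_mm = truth$voxel_size_mm,
    regions = truth$regions, amplitudes = as.list(truth$amplitudes),
    seed = truth$seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

CONFIG_KEYS <- c("grid_shape", "voxel_size_mm", "n_subjects", "runs_per_session",
                 "volumes_per_run", "tr", "sigma", "ar1", "drift_amplitude",
                 "regions", "amplitudes", "searchlight_radius", "min_voxels",
                 "alpha", "q", "cluster_k", "voxel_p", "t_threshold",
                 "n_permutations", "connectivity", "smooth_fwhm_mm",
                 "roi_radius_voxels", "tasks", "seed", "out_dir")

#' Read a pipeline configuration from YAML
#'
#' Unknown keys trigger a warning (never a silent ignore); known keys override
#' the defaults of [pipeline_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown)) {
    warning("unknown config key(s) ignored: ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw[intersect(names(raw), CONFIG_KEYS)])
}
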