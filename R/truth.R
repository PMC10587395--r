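#' Spherical region specification (voxel units)
#'
#' @param center length-3 voxel coordinate (1-based) of the sphere centre.
#' @param radius radius in voxel units.
#' @return a `region_spec` usable in [ground_truth_config()].
#' @export
region_sphere <- function(center, radius) {
  stopifnot(length(center) == 3, radius >= 0)
  structure(list(center = as.numeric(center), radius = radius),
            class = "region_spec")
}

resolve_region <- function(spec, grid_shape) {
  if (inherits(spec, "region_spec")) {
    g <- expand.grid(i = seq_len(grid_shape[1]), j = seq_len(grid_shape[2]),
                     k = seq_len(grid_shape[3]))
    d2 <- (g$i - spec$center[1])^2 + (g$j - spec$center[2])^2 +
      (g$k - spec$center[3])^2
    vox_to_index(as.matrix(g[d2 <= spec$radius^2 + 1e-9, ]), grid_shape)
  } else {
    idx <- as.integer(spec)
    if (any(idx < 1 | idx > prod(grid_shape))) {
      stop("region voxel indices outside the grid", call. = FALSE)
    }
    idx
  }
}

REGION_NAMES <- c("modality_region", "emotion_face_region",
                  "emotion_body_region", "emotion_voice_region",
                  "supramodal_emotion_region")

#' Ground-truth configuration for pattern simulation
#'
#' Encodes the hypothesis space the decoding pipeline probes. Each named
#' region carries multivoxel patterns with a specific structure:
#' `modality_region` has one pattern per stimulus type (shared across
#' emotions), so only modality is decodable there; `emotion_face_region` /
#' `emotion_body_region` / `emotion_voice_region` carry independent per-emotion
#' patterns evoked only by that stimulus type (modality-specific emotion
#' codes); `supramodal_emotion_region` carries per-emotion patterns that are
#' identical whichever stimulus type evoked them -- the signature cross-modal
#' decoding is designed to detect.
#'
#' @param grid_shape length-3 voxel grid dimensions.
#' @param voxel_size_mm voxel size in mm (scalar or length 3).
#' @param regions named list of [region_sphere()] specs or voxel index vectors;
#'   names must come from the five region roles above.
#' @param amplitudes named numeric scale factor per region (default 1). The
#'   pattern vectors are unit-norm over the region, so an amplitude `a` over an
#'   `n`-voxel region gives per-voxel signal RMS `a / sqrt(n)`.
#' @param brain_mask optional logical array; defaults to the full grid.
#' @param allow_overlap allow regions to share voxels.
#' @param origin_mm optional mm coordinate of voxel (1,1,1) for the affine.
#' @return a `truth_config` list.
#' @export
ground_truth_config <- function(grid_shape = c(24, 24, 24), voxel_size_mm = 2,
                                regions = list(), amplitudes = NULL,
                                brain_mask = NULL, allow_overlap = FALSE,
                                origin_mm = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  if (length(regions) && (is.null(names(regions)) ||
                          !all(names(regions) %in% REGION_NAMES))) {
    stop("region names must be one of: ", paste(REGION_NAMES, collapse = ", "),
         call. = FALSE)
  }
  amp <- stats::setNames(rep(1, length(regions)), names(regions))
  if (!is.null(amplitudes)) {
    bad <- setdiff(names(amplitudes), names(regions))
    if (length(bad)) stop("amplitude given for unknown region: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    amp[names(amplitudes)] <- amplitudes
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 regions = regions, amplitudes = amp, brain_mask = brain_mask,
                 allow_overlap = isTRUE(allow_overlap), origin_mm = origin_mm),
            class = "truth_config")
}

unit_pattern <- function(n) {
  if (n < 2) stop("pattern regions need at least 2 voxels", call. = FALSE)
  v <- stats::rnorm(n)
  v <- v - mean(v)
  v / sqrt(sum(v^2))
}

#' Draw ground-truth condition patterns
#'
#' Pattern vectors are drawn as zero-mean, unit-L2-norm Gaussian vectors over
#' each region's voxels, then scaled by the region amplitude at simulation
#' time. The supramodal constraint (identical emotion patterns across stimulus
#' types) is enforced by construction.
#'
#' @param config a [ground_truth_config()].
#' @param seed integer seed.
#' @param emotions,stimulus_types condition labels (defaults match
#'   [experiment_design()]).
#' @return a `ground_truth` object: grid geometry, brain mask, region voxel
#'   sets, and per-region 12 x n-voxel condition pattern matrices (rows named
#'   `<stimulus_type>_<emotion>`).
#' @export
simulate_patterns <- function(config, seed,
                              emotions = c("anger", "happy", "neutral", "fear"),
                              stimulus_types = c("face", "body", "voice")) {
  stopifnot(inherits(config, "truth_config"))
  set.seed(seed)
  gs <- config$grid_shape
  mask <- config$brain_mask %||% array(TRUE, gs)
  stopifnot(identical(dim(mask), gs))
  mask_idx <- which(mask)
  regions <- lapply(config$regions, resolve_region, grid_shape = gs)
  for (nm in names(regions)) {
    if (!all(regions[[nm]] %in% mask_idx)) {
      stop("region '", nm, "' is not a subset of the brain mask", call. = FALSE)
    }
  }
  if (!config$allow_overlap && length(regions) > 1) {
    nms <- names(regions)
    for (a in seq_along(nms)[-1]) for (b in seq_len(a - 1)) {
      if (length(intersect(regions[[nms[a]]], regions[[nms[b]]]))) {
        stop("regions '", nms[a], "' and '", nms[b],
             "' overlap; set allow_overlap = TRUE to permit this", call. = FALSE)
      }
    }
  }
  grid <- expand.grid(stimulus_type = stimulus_types, emotion = emotions,
                      stringsAsFactors = FALSE)
  conditions <- paste(grid$stimulus_type, grid$emotion, sep = "_")
  patterns <- list()
  for (nm in names(regions)) {
    nvox <- length(regions[[nm]])
    P <- matrix(0, length(conditions), nvox,
                dimnames = list(conditions, NULL))
    if (nm == "modality_region") {
      for (st in stimulus_types) {
        v <- unit_pattern(nvox)
        P[grid$stimulus_type == st, ] <- matrix(v, sum(grid$stimulus_type == st),
                                                nvox, byrow = TRUE)
      }
    } else if (nm == "supramodal_emotion_region") {
      for (em in emotions) {
        v <- unit_pattern(nvox)
        P[grid$emotion == em, ] <- matrix(v, sum(grid$emotion == em), nvox,
                                          byrow = TRUE)
      }
    } else {
      st <- sub("^emotion_(.*)_region$", "\\1", nm)
      for (em in emotions) {
        P[paste(st, em, sep = "_"), ] <- unit_pattern(nvox)
      }
    }
    patterns[[nm]] <- P
  }
  structure(list(
    grid_shape = gs, voxel_size_mm = config$voxel_size_mm,
    affine = grid_affine(gs, config$voxel_size_mm, config$origin_mm),
    brain_mask = mask, regions = regions, patterns = patterns,
    amplitudes = config$amplitudes, emotions = emotions,
    stimulus_types = stimulus_types, seed = seed
  ), class = "ground_truth")
}

#' Noise-free response amplitude of every trial at every masked voxel
#'
#' @param truth a `ground_truth` from [simulate_patterns()].
#' @param events event rows (catch trials contribute zero amplitude).
#' @return trials x masked-voxels amplitude matrix.
#' @export
trial_amplitudes <- function(truth, events) {
  mask_idx <- which(truth$brain_mask)
  A <- matrix(0, nrow(events), length(mask_idx))
  cond <- paste(events$stimulus_type, events$emotion, sep = "_")
  live <- !events$is_catch
  for (nm in names(truth$regions)) {
    cols <- match(truth$regions[[nm]], mask_idx)
    P <- truth$patterns[[nm]]
    A[live, cols] <- A[live, cols, drop = FALSE] +
      truth$amplitudes[[nm]] * P[cond[live], , drop = FALSE]
  }
  A
}
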