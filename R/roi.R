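#' The packaged ROI peak table
#'
#' Peak mm coordinates (Talairach convention) and reported sizes for the
#' regions probed in the ROI analysis: early visual cortex, FFA, EBA,
#' bilateral A1, MPFC, pSTS and bilateral amygdala. Bilateral regions appear
#' as one row per hemisphere sharing an `roi` name and are combined by mask
#' union when spheres are built.
#'
#' @param path optional alternative TSV (columns `roi`, `part`, `size_voxels`,
#'   `x`, `y`, `z`).
#' @return data frame of peak locations.
#' @export
roi_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "roi_peaks.tsv",
                                package = "emodecode", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Spherical ROI mask at a mm coordinate
#'
#' Maps the mm centre through the inverse affine and keeps the voxels whose
#' centres lie within `radius_voxels` (voxel units) of it. A radius of 0
#' returns the single nearest voxel.
#'
#' @param center_mm length-3 mm coordinate.
#' @param radius_voxels sphere radius in voxel units.
#' @param grid_shape length-3 grid dimensions.
#' @param affine 4 x 4 voxel-to-mm affine.
#' @param brain_mask optional logical array to intersect with.
#' @param name ROI name used in error messages.
#' @return integer grid voxel indices.
#' @export
sphere_roi <- function(center_mm, radius_voxels = 5, grid_shape, affine,
                       brain_mask = NULL, name = "ROI") {
  cv <- drop(mm_to_vox(center_mm, affine))
  if (any(cv < 0.5) || any(cv > grid_shape + 0.5)) {
    stop("ROI '", name, "': centre falls outside the grid", call. = FALSE)
  }
  if (radius_voxels == 0) {
    idx <- vox_to_index(pmin(pmax(round(cv), 1), grid_shape), grid_shape)
  } else {
    lo <- pmax(1, floor(cv - radius_voxels))
    hi <- pmin(grid_shape, ceiling(cv + radius_voxels))
    g <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
    d2 <- (g$i - cv[1])^2 + (g$j - cv[2])^2 + (g$k - cv[3])^2
    idx <- vox_to_index(as.matrix(g[d2 <= radius_voxels^2 + 1e-9, ]),
                        grid_shape)
  }
  if (!is.null(brain_mask)) idx <- idx[brain_mask[idx]]
  if (length(idx) == 0) {
    stop("ROI '", name, "': empty intersection with the brain mask",
         call. = FALSE)
  }
  sort(idx)
}

#' Build all ROI masks from a peak table
#'
#' One mask per distinct `roi` name; hemispheric parts (rows sharing a name)
#' are united into a single bilateral mask, as done for the amygdala and A1.
#'
#' @param table a [roi_table()]-style data frame.
#' @param grid_shape,affine grid geometry.
#' @param radius_voxels sphere radius (per-ROI configurable by recycling).
#' @param brain_mask optional logical array.
#' @return named list of voxel index vectors.
#' @export
roi_masks <- function(table, grid_shape, affine, radius_voxels = 5,
                      brain_mask = NULL) {
  radius_voxels <- rep_len(radius_voxels, nrow(table))
  out <- list()
  for (i in seq_len(nrow(table))) {
    idx <- sphere_roi(c(table$x[i], table$y[i], table$z[i]), radius_voxels[i],
                      grid_shape, affine, brain_mask, name = table$roi[i])
    nm <- table$roi[i]
    out[[nm]] <- sort(unique(c(out[[nm]], idx)))
  }
  out
}

#' 16-condition labels for ROI analyses
#'
#' Body and face conditions by emotion, plus voice conditions split by the
#' session they were recorded in, in the mandated block order: body, face,
#' voice session 1, voice session 2, each anger / happy / neutral / fear.
#'
#' @param emotions ordered emotion labels.
#' @return character vector of 16 condition names.
#' @export
roi_condition_order <- function(emotions = c("anger", "happy", "neutral", "fear")) {
  blocks <- c("body", "face", "voice_s1", "voice_s2")
  as.vector(t(outer(blocks, emotions, paste, sep = "_")))
}

roi_condition_of <- function(labels) {
  ifelse(labels$stimulus_type == "voice",
         paste0("voice_s", labels$session, "_", labels$emotion),
         paste(labels$stimulus_type, labels$emotion, sep = "_"))
}

#' Condition-mean responses in an ROI
#'
#' Mean trial beta over the ROI voxels, then over the trials of each of the
#' 16 conditions, for one subject.
#'
#' @param betas a `trial_beta_set`.
#' @param roi grid voxel indices of the ROI.
#' @param emotions ordered emotion labels.
#' @return named numeric vector of 16 condition means (NA for empty cells,
#'   flagged by an `empty_conditions` attribute -- never silently zero).
#' @export
condition_means <- function(betas, roi,
                            emotions = c("anger", "happy", "neutral", "fear")) {
  cols <- match(roi, which(betas$brain_mask))
  if (anyNA(cols)) stop("ROI voxels outside the beta mask", call. = FALSE)
  per_trial <- rowMeans(betas$betas[, cols, drop = FALSE])
  cond <- roi_condition_of(betas$labels)
  order16 <- roi_condition_order(emotions)
  m <- vapply(order16, function(cn) {
    sel <- cond == cn
    if (!any(sel)) NA_real_ else mean(per_trial[sel])
  }, numeric(1))
  empty <- order16[is.na(m)]
  if (length(empty)) attr(m, "empty_conditions") <- empty
  m
}

#' Group mean and standard error of ROI condition means
#'
#' @param betas_list per-subject `trial_beta_set`s.
#' @param roi grid voxel indices.
#' @param emotions ordered emotion labels.
#' @return data frame: condition, mean, se (sd across subjects / sqrt(n)).
#' @export
group_condition_means <- function(betas_list, roi,
                                  emotions = c("anger", "happy", "neutral", "fear")) {
  M <- do.call(rbind, lapply(betas_list, condition_means, roi = roi,
                             emotions = emotions))
  data.frame(condition = colnames(M),
             mean = colMeans(M),
             se = apply(M, 2, stats::sd) / sqrt(nrow(M)),
             row.names = NULL)
}

#' Condition-averaged multivoxel patterns in an ROI
#'
#' @inheritParams condition_means
#' @return 16 x ROI-voxels matrix of condition-averaged betas in the mandated
#'   block order.
#' @export
condition_patterns <- function(betas, roi,
                               emotions = c("anger", "happy", "neutral", "fear")) {
  cols <- match(roi, which(betas$brain_mask))
  if (anyNA(cols)) stop("ROI voxels outside the beta mask", call. = FALSE)
  X <- betas$betas[, cols, drop = FALSE]
  cond <- roi_condition_of(betas$labels)
  order16 <- roi_condition_order(emotions)
  P <- do.call(rbind, lapply(order16, function(cn) {
    sel <- cond == cn
    if (!any(sel)) rep(NA_real_, ncol(X)) else colMeans(X[sel, , drop = FALSE])
  }))
  rownames(P) <- order16
  P
}
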