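gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  k / sum(k)
}

conv_axis1 <- function(M, k) {
  # zero-padded 1-D convolution down the rows of a matrix
  if (length(k) == 1) return(M * k)
  r <- (length(k) - 1) / 2
  n <- nrow(M)
  pad <- rbind(matrix(0, r, ncol(M)), M, matrix(0, r, ncol(M)))
  out <- matrix(0, n, ncol(M))
  for (j in seq_along(k)) {
    out <- out + k[j] * pad[j:(j + n - 1), , drop = FALSE]
  }
  out
}

#' Gaussian spatial smoothing of a 3-D volume
#'
#' Separable Gaussian filter with per-axis standard deviation
#' `fwhm / (2 sqrt(2 ln 2))` converted to voxel units, honouring anisotropic
#' voxel sizes. Zero padding at the boundary; a FWHM of 0 returns the input
#' unchanged.
#'
#' @param volume 3-D numeric array.
#' @param fwhm_mm full width at half maximum in mm.
#' @param voxel_size_mm voxel edge lengths in mm (scalar or length 3).
#' @return smoothed array of the same dimensions.
#' @export
smooth_volume <- function(volume, fwhm_mm = 6, voxel_size_mm = 2) {
  stopifnot(length(dim(volume)) == 3, fwhm_mm >= 0)
  if (fwhm_mm == 0) return(volume)
  vs <- rep_len(voxel_size_mm, 3)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs
  d <- dim(volume)
  out <- volume
  for (ax in 1:3) {
    k <- gauss_kernel_1d(sigma_vox[ax])
    perm <- c(ax, setdiff(1:3, ax))
    M <- matrix(aperm(out, perm), d[ax])
    M <- conv_axis1(M, k)
    out <- aperm(array(M, d[perm]), order(perm))
  }
  out
}

#' Smooth every volume of a run
#'
#' Applies [smooth_volume()] frame by frame on the full grid (off-mask voxels
#' treated as zero) and restores the masked matrix layout.
#'
#' @param run a `bold_run`.
#' @param fwhm_mm smoothing kernel FWHM in mm.
#' @return a `bold_run` with smoothed data.
#' @export
smooth_bold_run <- function(run, fwhm_mm = 6) {
  if (fwhm_mm == 0) return(run)
  mask_idx <- which(run$brain_mask)
  vol <- array(0, run$grid_shape)
  for (t in seq_len(nrow(run$data))) {
    vol[mask_idx] <- run$data[t, ]
    sm <- smooth_volume(vol, fwhm_mm, run$voxel_size_mm)
    run$data[t, ] <- sm[mask_idx]
  }
  run
}
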