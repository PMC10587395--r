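`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive reproducible stage seeds from a master seed
#'
#' Every stochastic stage (schedule, patterns, per-run noise, permutations)
#' receives its own seed drawn from a stream initialised with the master seed,
#' so stages are independently reproducible: the k-th derived seed is the same
#' whatever subset of stages is re-run.
#'
#' @param master_seed single integer-valued seed.
#' @param n number of seeds to derive.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(length(master_seed) == 1, is.finite(master_seed), n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed %% (.Machine$integer.max - 1L)))
  sample.int(.Machine$integer.max - 1L, n)
}

# linear index <-> (i, j, k) helpers on a 3-D grid
vox_to_index <- function(ijk, grid_shape) {
  ijk <- matrix(as.integer(ijk), ncol = 3)
  (ijk[, 3] - 1L) * grid_shape[1] * grid_shape[2] +
    (ijk[, 2] - 1L) * grid_shape[1] + ijk[, 1]
}

index_to_vox <- function(idx, grid_shape) {
  idx0 <- as.integer(idx) - 1L
  i <- idx0 %% grid_shape[1]
  j <- (idx0 %/% grid_shape[1]) %% grid_shape[2]
  k <- idx0 %/% (grid_shape[1] * grid_shape[2])
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

#' Default affine for a simulated grid
#'
#' Diagonal voxel-size scaling with the grid centred on the origin, so mm
#' coordinates behave like a (toy) stereotaxic frame.
#'
#' @param grid_shape integer length-3 grid dimensions.
#' @param voxel_size_mm voxel edge length(s) in mm (scalar or length 3).
#' @param origin_mm optional mm coordinate of voxel (1,1,1); defaults to
#'   centring the grid.
#' @return 4 x 4 affine matrix mapping 1-based voxel indices to mm.
#' @export
grid_affine <- function(grid_shape, voxel_size_mm = 2, origin_mm = NULL) {
  vs <- rep_len(voxel_size_mm, 3)
  origin <- origin_mm %||% (-(grid_shape - 1) / 2 * vs)
  aff <- diag(4)
  diag(aff)[1:3] <- vs
  # voxel index 1 maps to origin: mm = (idx - 1) * vs + origin
  aff[1:3, 4] <- origin - vs
  aff
}

vox_to_mm <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3)
  t(affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

mm_to_vox <- function(mm, affine) {
  mm <- matrix(mm, ncol = 3)
  t(solve(affine) %*% rbind(t(mm), 1))[, 1:3, drop = FALSE]
}
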