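#' Integer voxel offsets of a searchlight sphere
#'
#' All integer offsets with squared Euclidean norm at most `radius^2` on the
#' voxel lattice (isotropic voxel units, matching a radius stated in voxels),
#' in deterministic lexicographic order.
#'
#' @param radius_voxels sphere radius in voxels (>= 0).
#' @return integer matrix with columns dx, dy, dz.
#' @export
sphere_offsets <- function(radius_voxels) {
  stopifnot(radius_voxels >= 0)
  r <- floor(radius_voxels)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= radius_voxels^2 + 1e-9, c("dx", "dy", "dz")]
  g <- g[order(g$dx, g$dy, g$dz), ]
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, c("dx", "dy", "dz"))
  storage.mode(m) <- "integer"
  m
}

#' Searchlight specification
#'
#' @param radius_voxels sphere radius in voxel units.
#' @param min_voxels minimum sphere-mask intersection for a centre to be
#'   decodable; smaller centres are undefined (NA), never zero-filled.
#' @return a `searchlight_spec`.
#' @export
searchlight_spec <- function(radius_voxels = 5, min_voxels = 10) {
  stopifnot(radius_voxels >= 0, min_voxels >= 1)
  structure(list(radius_voxels = radius_voxels,
                 min_voxels = as.integer(min_voxels)),
            class = "searchlight_spec")
}

#' Sparse centre-by-voxel searchlight membership matrix
#'
#' Row i marks the masked voxels inside the sphere centred on masked voxel i.
#' Multiplying it into a voxels x k matrix sums any per-voxel quantity over
#' every sphere at once, which is how the searchlight GNB accumulates
#' per-voxel Gaussian log densities.
#'
#' @param grid_shape length-3 grid dimensions.
#' @param mask logical array (default: whole grid).
#' @param spec a [searchlight_spec()].
#' @return list: `S` (sparse n_mask x n_mask matrix), `n_in_sphere`, `defined`
#'   (centres meeting `min_voxels`), `mask_idx`.
#' @export
searchlight_matrix <- function(grid_shape, mask = NULL, spec = searchlight_spec()) {
  mask <- mask %||% array(TRUE, grid_shape)
  mask_idx <- which(mask)
  pos <- index_to_vox(mask_idx, grid_shape)
  off <- sphere_offsets(spec$radius_voxels)
  n <- length(mask_idx)
  in_mask <- logical(prod(grid_shape))
  in_mask[mask_idx] <- TRUE
  col_of <- integer(prod(grid_shape))
  col_of[mask_idx] <- seq_len(n)
  ii <- vector("list", nrow(off))
  jj <- vector("list", nrow(off))
  for (o in seq_len(nrow(off))) {
    p <- pos
    p[, 1] <- p[, 1] + off[o, 1]
    p[, 2] <- p[, 2] + off[o, 2]
    p[, 3] <- p[, 3] + off[o, 3]
    ok <- p[, 1] >= 1 & p[, 1] <= grid_shape[1] &
      p[, 2] >= 1 & p[, 2] <= grid_shape[2] &
      p[, 3] >= 1 & p[, 3] <= grid_shape[3]
    lin <- vox_to_index(p[ok, , drop = FALSE], grid_shape)
    keep <- in_mask[lin]
    ii[[o]] <- which(ok)[keep]
    jj[[o]] <- col_of[lin[keep]]
  }
  S <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                            dims = c(n, n))
  n_in_sphere <- Matrix::rowSums(S)
  list(S = S, n_in_sphere = n_in_sphere,
       defined = n_in_sphere >= spec$min_voxels, mask_idx = mask_idx,
       grid_shape = grid_shape, spec = spec)
}

# Per-centre GNB predictions for one train/test split, vectorised across
# centres: voxelwise class log densities are summed over each sphere through
# the sparse membership matrix. Variance floor as in gnb_fit, with the global
# mean taken over the whole map's class variances.
sl_fold_predict <- function(Xtr, ytr, Xte, sl, levels, var_floor_frac = 1e-9) {
  n_te <- nrow(Xte)
  stats_by_class <- lapply(levels, function(cl) {
    xc <- Xtr[ytr == cl, , drop = FALSE]
    if (nrow(xc) < 2) {
      stop("insufficient data: class '", cl, "' has fewer than 2 training trials",
           call. = FALSE)
    }
    mu <- colMeans(xc)
    list(mu = mu, v = colMeans(xc^2) - mu^2,
         logprior = log(nrow(xc) / nrow(Xtr)))
  })
  gv <- mean(vapply(stats_by_class, function(s) mean(s$v), numeric(1)))
  floor_val <- max(var_floor_frac * gv, .Machine$double.xmin)
  best <- NULL
  best_cl <- NULL
  for (ci in seq_along(levels)) {
    st <- stats_by_class[[ci]]
    v <- pmax(st$v, floor_val)
    dev2 <- sweep(Xte, 2, st$mu)^2
    # voxels x test-trials log density terms
    L <- t(sweep(dev2, 2, 2 * v, "/") + matrix(0.5 * log(2 * pi * v),
                                               n_te, length(v), byrow = TRUE))
    P <- as.matrix(sl$S %*% (-L)) + st$logprior
    if (is.null(best)) {
      best <- P
      best_cl <- matrix(1L, nrow(P), ncol(P))
    } else {
      upd <- P > best    # strict: ties keep the earlier class
      best[upd] <- P[upd]
      best_cl[upd] <- ci
    }
  }
  matrix(levels[best_cl], nrow(best_cl), ncol(best_cl))
}

new_accuracy_map <- function(values, defined, task, sl, n_folds, betas) {
  values[!defined] <- NA_real_
  structure(list(values = values, defined = defined, task = task$name,
                 chance_level = task$chance_level, n_folds = n_folds,
                 mask_idx = sl$mask_idx, grid_shape = sl$grid_shape,
                 spec = sl$spec, affine = betas$affine),
            class = "accuracy_map")
}

check_class_balance <- function(y, runs, levels) {
  tab <- table(factor(y, levels = levels), runs)
  if (any(tab < 2)) {
    stop("task leaves fewer than 2 trials for some class within a run; ",
         "cannot cross-validate", call. = FALSE)
  }
}

#' Searchlight decoding with leave-one-run-out cross-validation
#'
#' For every masked centre voxel, decodes the task's labels from the trial
#' betas of the sphere-mask intersection with a Gaussian Naive Bayes
#' classifier, averaging pooled accuracy over leave-one-run-out folds.
#' Centres whose sphere retains fewer than `min_voxels` masked voxels are NA.
#'
#' @param betas a `trial_beta_set` for one subject.
#' @param task a `decoding_task` with `kind = "cv"`.
#' @param spec a [searchlight_spec()].
#' @param sl optional precomputed [searchlight_matrix()] (reused across
#'   subjects and tasks for speed).
#' @param relabel optional replacement label vector aligned with the task's
#'   filtered trials (used by the permutation test).
#' @return an `accuracy_map`.
#' @export
searchlight_decode <- function(betas, task, spec = searchlight_spec(),
                               sl = NULL, relabel = NULL) {
  stopifnot(inherits(task, "decoding_task"), task$kind == "cv")
  sl <- sl %||% searchlight_matrix(betas$grid_shape, betas$brain_mask, spec)
  keep <- which(task$filter(betas$labels))
  X <- betas$betas[keep, , drop = FALSE]
  y <- relabel %||% task$label_fun(betas$labels[keep, , drop = FALSE])
  stopifnot(length(y) == nrow(X))
  runs <- betas$labels$run[keep]
  check_class_balance(y, runs, task$levels)
  folds <- leave_one_run_out_folds(runs)
  acc <- matrix(0, nrow(sl$S), length(folds))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    pred <- sl_fold_predict(X[fold$train, , drop = FALSE], y[fold$train],
                            X[fold$test, , drop = FALSE], sl, task$levels)
    acc[, f] <- rowMeans(pred == matrix(y[fold$test], nrow(pred),
                                        length(fold$test), byrow = TRUE))
  }
  new_accuracy_map(rowMeans(acc), sl$defined, task, sl, length(folds), betas)
}

#' Cross-modal searchlight decoding (single split)
#'
#' Fits on all trials passing the task's train filter and evaluates on all
#' trials passing its test filter -- no cross-validation, since train and test
#' sets are disjoint by construction (e.g. train on body trials, test on the
#' voice trials of the body session). All four direction pairs are available
#' through [crossmodal_task_set()].
#'
#' @param betas a `trial_beta_set`.
#' @param task a `decoding_task` with `kind = "crossmodal"`.
#' @inheritParams searchlight_decode
#' @return an `accuracy_map` with `n_folds = 1`.
#' @export
crossmodal_decode <- function(betas, task, spec = searchlight_spec(),
                              sl = NULL) {
  stopifnot(inherits(task, "decoding_task"), task$kind == "crossmodal")
  sl <- sl %||% searchlight_matrix(betas$grid_shape, betas$brain_mask, spec)
  tr_idx <- which(task$train_filter(betas$labels))
  te_idx <- which(task$test_filter(betas$labels))
  if (length(intersect(tr_idx, te_idx))) {
    stop("train and test trial sets overlap", call. = FALSE)
  }
  ytr <- task$label_fun(betas$labels[tr_idx, , drop = FALSE])
  yte <- task$label_fun(betas$labels[te_idx, , drop = FALSE])
  if (!all(task$levels %in% ytr) || !all(task$levels %in% yte)) {
    stop("train and test sets must each contain every class", call. = FALSE)
  }
  pred <- sl_fold_predict(betas$betas[tr_idx, , drop = FALSE], ytr,
                          betas$betas[te_idx, , drop = FALSE], sl, task$levels)
  acc <- rowMeans(pred == matrix(yte, nrow(pred), length(yte), byrow = TRUE))
  new_accuracy_map(acc, sl$defined, task, sl, 1L, betas)
}

#' Mean accuracy over the defined voxels of a map
#'
#' @param map an `accuracy_map`.
#' @param voxels optional restriction to grid voxel indices.
#' @return mean accuracy (NA-safe).
#' @export
map_mean_accuracy <- function(map, voxels = NULL) {
  v <- map$values
  if (!is.null(voxels)) v <- v[map$mask_idx %in% voxels]
  mean(v, na.rm = TRUE)
}
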