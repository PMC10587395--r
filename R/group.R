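stack_maps <- function(maps) {
  stopifnot(length(maps) >= 2)
  V <- length(maps[[1]]$values)
  M <- do.call(rbind, lapply(maps, function(m) {
    stopifnot(length(m$values) == V)
    m$values
  }))
  M
}

#' One-sample t-test of accuracy maps against chance
#'
#' Per voxel, a one-sample t of (accuracy - chance) across subjects with
#' one-sided p (accuracy above chance being the only direction of interest).
#' Voxels defined in fewer than two subjects are undefined. A voxel where
#' every subject sits exactly at chance is reported as t = 0, p = 0.5.
#'
#' @param maps list of per-subject `accuracy_map`s on one grid.
#' @param chance_level analytic chance probability (taken from the first map's
#'   task when omitted).
#' @return a `group_stat_map`: per-voxel `t`, one-sided `p`, `df`, `n`.
#' @export
ttest_vs_chance <- function(maps, chance_level = NULL) {
  chance_level <- chance_level %||% maps[[1]]$chance_level
  M <- stack_maps(maps) - chance_level
  n <- colSums(!is.na(M))
  mu <- colMeans(M, na.rm = TRUE)
  sd <- apply(M, 2, stats::sd, na.rm = TRUE)
  t <- mu / (sd / sqrt(n))
  t[sd == 0 & mu == 0] <- 0
  t[n < 2] <- NA_real_
  df <- n - 1
  p <- stats::pt(t, df, lower.tail = FALSE)
  p[!is.na(sd) & sd == 0 & !is.na(mu) & mu > 0] <- 0
  structure(list(t = t, p = p, df = df, n = n, chance_level = chance_level,
                 mask_idx = maps[[1]]$mask_idx,
                 grid_shape = maps[[1]]$grid_shape,
                 affine = maps[[1]]$affine,
                 task = maps[[1]]$task),
            class = "group_stat_map")
}

#' Family-wise error correction of a group map
#'
#' `bonferroni` rejects where p <= alpha / m over the m defined voxels (the
#' default). `max_stat_permutation` rejects where t exceeds the (1 - alpha)
#' quantile of the permutation distribution of the map-wise maximum t, given a
#' list of t-maps computed under permuted labels (e.g. the per-permutation
#' maps of [permutation_group_test()]).
#'
#' @param stat_map a `group_stat_map`.
#' @param alpha family-wise error level.
#' @param method `"bonferroni"` or `"max_stat_permutation"`.
#' @param perm_t list of per-permutation t vectors (required for the
#'   permutation method).
#' @return list: logical `reject` per voxel, the `threshold` used, `method`,
#'   `m` (defined voxels).
#' @export
fwe_correct <- function(stat_map, alpha = 0.05,
                        method = c("bonferroni", "max_stat_permutation"),
                        perm_t = NULL) {
  method <- match.arg(method)
  defined <- !is.na(stat_map$p)
  m <- sum(defined)
  if (method == "bonferroni") {
    reject <- !is.na(stat_map$p) & stat_map$p <= alpha / m
    thr <- alpha / m
  } else {
    if (is.null(perm_t)) {
      stop("max_stat_permutation requires permutation t-maps (perm_t)",
           call. = FALSE)
    }
    max_t <- vapply(perm_t, function(tv) max(tv, na.rm = TRUE), numeric(1))
    thr <- stats::quantile(max_t, 1 - alpha, names = FALSE, type = 1)
    reject <- !is.na(stat_map$t) & stat_map$t > thr
  }
  list(reject = reject, threshold = thr, method = method, m = m,
       alpha = alpha)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjusted p-values (via `stats::p.adjust`) and the rejection set at
#' level `q`; NAs are carried through.
#'
#' @param p_values p-values in \[0, 1\].
#' @param q FDR level.
#' @return list with `reject` and monotone `p_adjusted`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  adj <- stats::p.adjust(p_values, method = "BH")
  list(reject = !is.na(adj) & adj <= q, p_adjusted = adj, q = q)
}

connectivity_offsets <- function(connectivity = 26) {
  connectivity <- match.arg(as.character(connectivity), c("26", "18", "6"))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(off != 0)
  keep <- switch(connectivity,
                 "6" = nz == 1,
                 "18" = nz >= 1 & nz <= 2,
                 "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

#' Cluster-extent thresholding of a group map
#'
#' Thresholds the map at an uncorrected voxel p, labels the surviving voxels
#' into connected components (26-neighbour connectivity by default), removes
#' components smaller than `extent_k`, and tabulates each cluster's size, peak
#' t, peak p and peak coordinates. When permutation t-maps are supplied, a
#' cluster-level p is added as the fraction of permutations whose largest
#' supra-threshold cluster is at least as large.
#'
#' @param stat_map a `group_stat_map`.
#' @param voxel_p_threshold uncorrected voxel-level p threshold.
#' @param extent_k minimum cluster size in voxels.
#' @param connectivity 6, 18 or 26.
#' @param perm_t optional list of permutation t vectors for cluster-level p.
#' @return list: `table` (one row per surviving cluster, largest first) and
#'   `labels` (cluster id per masked voxel, 0 outside clusters).
#' @export
cluster_threshold <- function(stat_map, voxel_p_threshold = 0.001,
                              extent_k = 25, connectivity = 26,
                              perm_t = NULL) {
  stopifnot(voxel_p_threshold > 0, voxel_p_threshold <= 1, extent_k >= 1)
  supra <- !is.na(stat_map$p) & stat_map$p <= voxel_p_threshold
  labels <- label_components(stat_map$mask_idx[supra], stat_map$grid_shape,
                             connectivity)
  full <- integer(length(stat_map$mask_idx))
  full[supra] <- labels
  sizes <- if (length(labels)) tabulate(labels) else integer(0)
  keep_ids <- which(sizes >= extent_k)
  # relabel surviving clusters by decreasing size
  keep_ids <- keep_ids[order(sizes[keep_ids], decreasing = TRUE)]
  out_labels <- integer(length(stat_map$mask_idx))
  rows <- vector("list", length(keep_ids))
  crit_t <- NULL
  if (!is.null(perm_t)) {
    n_defined <- sum(!is.na(stat_map$p))
    df <- max(stat_map$df, na.rm = TRUE)
    crit_t <- stats::qt(voxel_p_threshold, df, lower.tail = FALSE)
    perm_max_cluster <- vapply(perm_t, function(tv) {
      sup <- !is.na(tv) & tv > crit_t
      lab <- label_components(stat_map$mask_idx[sup], stat_map$grid_shape,
                              connectivity)
      if (length(lab)) max(tabulate(lab)) else 0L
    }, numeric(1))
  }
  for (i in seq_along(keep_ids)) {
    sel <- full == keep_ids[i]
    out_labels[sel] <- i
    tv <- stat_map$t[sel]
    peak <- which.max(tv)
    peak_vox <- stat_map$mask_idx[sel][peak]
    ijk <- index_to_vox(peak_vox, stat_map$grid_shape)
    mm <- if (!is.null(stat_map$affine)) vox_to_mm(ijk, stat_map$affine) else ijk
    rows[[i]] <- data.frame(
      cluster = i, size = sum(sel),
      cluster_p = if (is.null(perm_t)) NA_real_ else
        mean(perm_max_cluster >= sum(sel)),
      peak_t = tv[peak], peak_p = stat_map$p[sel][peak],
      x = mm[1], y = mm[2], z = mm[3]
    )
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), size = integer(0), cluster_p = numeric(0),
               peak_t = numeric(0), peak_p = numeric(0), x = numeric(0),
               y = numeric(0), z = numeric(0))
  list(table = tab, labels = out_labels,
       voxel_p_threshold = voxel_p_threshold, extent_k = extent_k,
       connectivity = connectivity)
}

# connected components of a voxel set via igraph on the adjacency graph
label_components <- function(vox_idx, grid_shape, connectivity = 26) {
  n <- length(vox_idx)
  if (n == 0) return(integer(0))
  off <- connectivity_offsets(connectivity)
  inset <- integer(prod(grid_shape))
  inset[vox_idx] <- seq_len(n)
  pos <- index_to_vox(vox_idx, grid_shape)
  edges <- vector("list", nrow(off))
  for (o in seq_len(nrow(off))) {
    p <- pos
    p[, 1] <- p[, 1] + off[o, 1]
    p[, 2] <- p[, 2] + off[o, 2]
    p[, 3] <- p[, 3] + off[o, 3]
    ok <- p[, 1] >= 1 & p[, 1] <= grid_shape[1] &
      p[, 2] >= 1 & p[, 2] <= grid_shape[2] &
      p[, 3] >= 1 & p[, 3] <= grid_shape[3]
    lin <- vox_to_index(p[ok, , drop = FALSE], grid_shape)
    nb <- inset[lin]
    hit <- nb > 0
    edges[[o]] <- cbind(which(ok)[hit], nb[hit])
  }
  E <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(matrix(as.character(E), ncol = 2),
                                   directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(seq_len(n)),
                                    igraph::V(g)$name))
  comp <- igraph::components(g)
  labs <- comp$membership[as.character(seq_len(n))]
  as.integer(labs)
}
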