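#' Shared-label permutation scheme
#'
#' Builds `n_permutations` relabelings of the emotion labels that every
#' participant shares (the same randomisations applied to all subjects, which
#' is what licenses the paired group-level comparison). Labels are shuffled
#' within run, so per-run class counts -- and hence fold balance under
#' leave-one-run-out cross-validation -- are preserved exactly by
#' construction; each draw is still verified and regenerated if it ever broke
#' balance.
#'
#' @param labels the trial label table shared by all subjects, already
#'   restricted to the task's trials (e.g.
#'   `betas$labels[task$filter(betas$labels), ]`).
#' @param task the `decoding_task` whose labels are permuted.
#' @param n_permutations number of shared label sets.
#' @param seed integer seed.
#' @return a `permutation_scheme`: `label_sets` is an
#'   `n_permutations` x trials character matrix.
#' @export
permutation_scheme <- function(labels, task, n_permutations = 100, seed = 1) {
  stopifnot(n_permutations >= 1)
  set.seed(seed)
  y <- task$label_fun(labels)
  runs <- labels$run
  sets <- matrix(NA_character_, n_permutations, length(y))
  per_run_tab <- table(runs, y, dnn = NULL)
  for (p in seq_len(n_permutations)) {
    repeat {
      perm <- y
      for (r in unique(runs)) {
        sel <- runs == r
        perm[sel] <- sample(y[sel])
      }
      if (identical(table(runs, perm, dnn = NULL), per_run_tab)) break
      warning("regenerating a permutation that broke class balance")
    }
    sets[p, ] <- perm
  }
  structure(list(label_sets = sets, n_permutations = n_permutations,
                 task = task$name, seed = seed, runs = runs, true_labels = y),
            class = "permutation_scheme")
}

#' Group-level permutation test of decoding accuracy
#'
#' For each shared permutation, reruns the full per-subject leave-one-run-out
#' searchlight decoding with the permuted labels, then compares true and
#' permuted accuracies with a paired t-test across subjects at every voxel.
#' The n per-permutation t-maps are averaged into a single group t-map and
#' thresholded (default t > 3.9).
#'
#' @param betas_list per-subject `trial_beta_set`s (shared schedule).
#' @param task a `decoding_task` with `kind = "cv"`.
#' @param spec a [searchlight_spec()].
#' @param scheme a [permutation_scheme()] built from the same task and trials.
#' @param t_threshold threshold applied to the averaged t-map.
#' @param true_maps optional precomputed per-subject true-label accuracy maps.
#' @return list: `t_avg` (averaged t per voxel), `exceed` (logical, averaged t
#'   above threshold), `perm_t` (list of per-permutation paired-t vectors,
#'   reusable by [fwe_correct()]'s max-statistic method), `true_maps`.
#' @export
permutation_group_test <- function(betas_list, task, spec, scheme,
                                   t_threshold = 3.9, true_maps = NULL) {
  stopifnot(inherits(scheme, "permutation_scheme"))
  n_sub <- length(betas_list)
  if (n_sub < 2) stop("at least 2 subjects are required", call. = FALSE)
  sl <- searchlight_matrix(betas_list[[1]]$grid_shape,
                           betas_list[[1]]$brain_mask, spec)
  true_maps <- true_maps %||% lapply(betas_list, searchlight_decode, task = task,
                                     spec = spec, sl = sl)
  true_M <- stack_maps(true_maps)
  perm_t <- vector("list", scheme$n_permutations)
  for (p in seq_len(scheme$n_permutations)) {
    perm_M <- do.call(rbind, lapply(betas_list, function(b) {
      searchlight_decode(b, task, spec, sl = sl,
                         relabel = scheme$label_sets[p, ])$values
    }))
    D <- true_M - perm_M
    mu <- colMeans(D)
    sd <- apply(D, 2, stats::sd)
    tv <- mu / (sd / sqrt(n_sub))
    tv[sd == 0 & mu == 0] <- 0
    perm_t[[p]] <- tv
  }
  t_avg <- Reduce(`+`, perm_t) / scheme$n_permutations
  list(t_avg = t_avg, exceed = !is.na(t_avg) & t_avg > t_threshold,
       t_threshold = t_threshold, perm_t = perm_t, true_maps = true_maps,
       mask_idx = true_maps[[1]]$mask_idx,
       grid_shape = true_maps[[1]]$grid_shape)
}
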