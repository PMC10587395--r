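# Shared fixtures, built in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

tiny_design <- function(runs_per_session = 2L) {
  experiment_design(runs_per_session = runs_per_session)
}

tiny_dataset <- function(seed = 42, regions = list(), amplitudes = NULL,
                         n_subjects = 3, sigma = 1, grid = c(8, 8, 8),
                         runs_per_session = 2L, ar1 = 0.3, drift = 1) {
  cfg <- sim_config(
    design = tiny_design(runs_per_session),
    truth = ground_truth_config(grid_shape = grid, regions = regions,
                                amplitudes = amplitudes),
    noise = noise_model(sigma = sigma, ar1 = ar1, drift_amplitude = drift),
    n_subjects = n_subjects
  )
  generate_dataset(cfg, seed)
}

betas_for <- function(ds) {
  lapply(ds$subjects, estimate_trial_betas, events = ds$events)
}

# 3 null subjects on an 8^3 grid, 4 runs: the workhorse for decoding tests
tiny_null_betas <- function() {
  memo_fixture("null_betas", betas_for(tiny_dataset(seed = 42)))
}

# voice-emotion signal planted in a radius-2 sphere
voice_region_spec <- function() list(emotion_voice_region = region_sphere(c(4, 4, 4), 2))

tiny_voice_betas <- function() {
  memo_fixture("voice_betas", {
    ds <- tiny_dataset(seed = 7, regions = voice_region_spec(),
                       amplitudes = c(emotion_voice_region = 6))
    list(betas = betas_for(ds), truth = ds$truth, events = ds$events)
  })
}

# a synthetic trial_beta_set with hand-built features (no GLM involved)
make_beta_set <- function(X, labels, grid = NULL) {
  grid <- grid %||% c(ceiling(ncol(X)^(1 / 3)), 1, 1)
  if (prod(grid) < ncol(X)) grid <- c(ncol(X), 1, 1)
  mask <- array(FALSE, grid)
  mask[seq_len(ncol(X))] <- TRUE
  structure(list(betas = X, labels = labels, grid_shape = grid,
                 brain_mask = mask, affine = grid_affine(grid),
                 voxel_size_mm = 2),
            class = "trial_beta_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- independent oracles -----------------------------------------------

# Bayes-rule GNB prediction via dnorm, looped (independent of gnb_predict)
oracle_gnb_predict <- function(model, x) {
  apply(x, 1, function(row) {
    lp <- vapply(seq_along(model$classes), function(ci) {
      model$log_priors[ci] +
        sum(stats::dnorm(row, model$means[ci, ],
                         sqrt(model$variances[ci, ]), log = TRUE))
    }, numeric(1))
    model$classes[which.max(lp)]
  })
}

# exhaustive step-up BH: reject all p <= the largest p(i) with p(i) <= i q / m
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  s <- sort(p)
  ok <- which(s <= seq_len(m) * q / m)
  if (!length(ok)) return(rep(FALSE, m))
  p <= s[max(ok)]
}

# queue-based flood fill over a voxel index set
oracle_flood_fill <- function(vox_idx, grid_shape, connectivity = 26) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(off != 0)
  off <- off[switch(as.character(connectivity),
                    "6" = nz == 1, "18" = nz >= 1 & nz <= 2, nz >= 1), ,
             drop = FALSE]
  n <- length(vox_idx)
  lab <- integer(n)
  pos <- emodecode:::index_to_vox(vox_idx, grid_shape)
  key <- new.env(parent = emptyenv())
  for (i in seq_len(n)) assign(as.character(vox_idx[i]), i, envir = key)
  cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s]) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (o in seq_len(nrow(off))) {
        p <- pos[v, ] + off[o, ]
        if (any(p < 1) || any(p > grid_shape)) next
        li <- emodecode:::vox_to_index(p, grid_shape)
        j <- mget(as.character(li), envir = key, ifnotfound = list(NULL))[[1]]
        if (!is.null(j) && lab[j] == 0L) {
          lab[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# labelings agree iff they induce the same partition
same_partition <- function(a, b) {
  length(a) == length(b) &&
    !is.unsorted(vapply(split(b, a), function(x) length(unique(x)), 1L)) &&
    all(vapply(split(b, a), function(x) length(unique(x)) == 1, TRUE)) &&
    all(vapply(split(a, b), function(x) length(unique(x)) == 1, TRUE))
}
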