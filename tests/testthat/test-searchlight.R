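test_that("sphere offsets match the brute-force lattice count", {
  expect_equal(nrow(sphere_offsets(0)), 1)
  expect_equal(nrow(sphere_offsets(1)), 7)
  # brute-force count of integer triples with x^2 + y^2 + z^2 <= r^2
  brute <- function(r) {
    g <- expand.grid(-r:r, -r:r, -r:r)
    sum(rowSums(g^2) <= r^2)
  }
  for (r in 2:5) expect_equal(nrow(sphere_offsets(r)), brute(r))
  expect_equal(nrow(sphere_offsets(5)), 515)
  # deterministic lexicographic order
  off <- sphere_offsets(2)
  expect_identical(off, off[order(off[, 1], off[, 2], off[, 3]), ])
})

test_that("the searchlight membership matrix counts sphere-mask intersections", {
  sl <- searchlight_matrix(c(12, 12, 12), spec = searchlight_spec(5, 10))
  centre <- emodecode:::vox_to_index(c(6, 6, 6), c(12, 12, 12))
  ci <- match(centre, sl$mask_idx)
  expect_equal(sl$n_in_sphere[ci], 515)   # fully interior sphere
  corner <- match(1, sl$mask_idx)
  expect_lt(sl$n_in_sphere[corner], 515)  # clipped at the boundary
  # min_voxels marks undefined centres
  sl2 <- searchlight_matrix(c(12, 12, 12), spec = searchlight_spec(5, 516))
  expect_false(any(sl2$defined))
})

test_that("a radius-0 searchlight equals per-voxel GNB decoding", {
  set.seed(3)
  n <- 48
  X <- matrix(rnorm(n * 8), n, 8)
  labels <- data.frame(emotion = rep(c("anger", "happy", "neutral", "fear"), n / 4),
                       stimulus_type = "voice", session = 1,
                       run = rep(1:4, each = n / 4), run_half = "auditory")
  X[labels$emotion == "anger", 3] <- X[labels$emotion == "anger", 3] + 2
  b <- make_beta_set(X, labels, grid = c(2, 2, 2))
  task <- task_emotion_all()
  map <- searchlight_decode(b, task, searchlight_spec(0, 1))
  # oracle: per-voxel gnb_fit / gnb_predict over the same folds
  folds <- leave_one_run_out_folds(labels$run)
  for (v in 1:8) {
    acc <- mean(vapply(folds, function(f) {
      m <- gnb_fit(X[f$train, v, drop = FALSE],
                   factor(labels$emotion[f$train], levels = task$levels))
      accuracy(gnb_predict(m, X[f$test, v, drop = FALSE])$class,
               labels$emotion[f$test])
    }, numeric(1)))
    expect_equal(map$values[v], acc, tolerance = 1e-12)
  }
})

test_that("accuracy maps are invariant to label-preserving trial reordering", {
  b <- tiny_null_betas()[[1]]
  task <- task_emotion_all()
  spec <- searchlight_spec(2, 5)
  m1 <- searchlight_decode(b, task, spec)
  set.seed(9)
  perm <- sample(nrow(b$betas))
  b2 <- b
  b2$betas <- b$betas[perm, ]
  b2$labels <- b$labels[perm, ]
  m2 <- searchlight_decode(b2, task, spec)
  expect_equal(m1$values, m2$values, tolerance = 1e-12)
})

test_that("undefined centres are NA and excluded from map summaries", {
  b <- tiny_null_betas()[[1]]
  # an 8^3 grid with radius 2 and a high min_voxels leaves corners undefined
  spec <- searchlight_spec(2, 33)
  m <- searchlight_decode(b, task_modality(), spec)
  expect_true(any(is.na(m$values)))
  expect_false(any(is.na(m$values[m$defined])))
  expect_false(is.na(map_mean_accuracy(m)))
  expect_true(all(m$values[m$defined] >= 0 & m$values[m$defined] <= 1))
})

test_that("within-modality signal is found in its region and nowhere else", {
  fx <- tiny_voice_betas()
  spec <- searchlight_spec(2, 5)
  region <- fx$truth$regions$emotion_voice_region
  maps <- lapply(fx$betas, searchlight_decode, task = task_emotion_within("voice"),
                 spec = spec)
  in_region <- mean(vapply(maps, map_mean_accuracy, numeric(1), voxels = region))
  outside <- setdiff(which(fx$truth$brain_mask), region)
  # exclude the searchlight halo around the region from the "outside" control
  halo <- unique(unlist(lapply(region, function(v) {
    p <- emodecode:::index_to_vox(v, fx$truth$grid_shape)
    off <- sphere_offsets(2)
    q <- sweep(off, 2, as.integer(p), "+")
    ok <- q[, 1] >= 1 & q[, 1] <= 8 & q[, 2] >= 1 & q[, 2] <= 8 &
      q[, 3] >= 1 & q[, 3] <= 8
    emodecode:::vox_to_index(q[ok, , drop = FALSE], fx$truth$grid_shape)
  })))
  far <- setdiff(outside, halo)
  out_acc <- mean(vapply(maps, map_mean_accuracy, numeric(1), voxels = far))
  expect_gt(in_region, 0.5)          # far above 25% chance
  expect_lt(abs(out_acc - 0.25), 0.05)
})

test_that("region accuracy is monotone in effect amplitude", {
  amplitudes <- c(0, 1.5, 3, 4.5, 6)
  d <- tiny_design(1L)
  spec <- searchlight_spec(1, 2)
  grid <- c(6, 6, 6)
  acc <- matrix(NA_real_, 10, length(amplitudes))
  for (s in 1:10) {
    ev <- build_design(d, 100 + s)
    for (k in seq_along(amplitudes)) {
      cfg <- ground_truth_config(grid_shape = grid, regions = voice_region_spec(),
                                 amplitudes = c(emotion_voice_region = amplitudes[k]))
      truth <- simulate_patterns(cfg, 50 + s)
      runs <- lapply(1:2, function(r) {
        simulate_run(ev[ev$run == r, ], truth, noise_model(1, 0.3, 0.5), d,
                     seed = 7000 + 10 * s + r)
      })
      b <- estimate_trial_betas(runs, ev)
      m <- searchlight_decode(b, task_emotion_within("voice"), spec)
      acc[s, k] <- map_mean_accuracy(m, voxels = truth$regions$emotion_voice_region)
    }
  }
  expect_true(all(diff(colMeans(acc)) > -0.01))
  expect_gt(colMeans(acc)[5], colMeans(acc)[1])
})

test_that("cross-modal decoding validates its trial sets", {
  b <- tiny_null_betas()[[1]]
  task <- task_emotion_crossmodal("body", "voice")
  # voice trials paired with body come from session 1 only
  te <- b$labels[task$test_filter(b$labels), ]
  expect_true(all(te$stimulus_type == "voice" & te$session == 1))
  tr <- b$labels[task$train_filter(b$labels), ]
  expect_true(all(tr$stimulus_type == "body"))
  m <- crossmodal_decode(b, task, searchlight_spec(2, 5))
  expect_equal(m$n_folds, 1)
  # overlapping train/test is refused
  bad <- task
  bad$test_filter <- task$train_filter
  expect_error(crossmodal_decode(b, bad, searchlight_spec(2, 5)), "overlap")
  expect_error(task_emotion_crossmodal("face", "body"), "pair voice")
})

test_that("a supramodal region supports cross-modal generalization; modality-specific signal does not", {
  spec <- searchlight_spec(2, 5)
  # modality-specific only: cross-modal stays at chance inside the voice region
  fx <- tiny_voice_betas()
  cm <- crossmodal_decode(fx$betas[[1]], task_emotion_crossmodal("body", "voice"), spec)
  expect_lt(abs(map_mean_accuracy(cm, fx$truth$regions$emotion_voice_region) - 0.25),
            0.1)
  # supramodal: both directions decode inside the planted region
  ds <- tiny_dataset(seed = 21,
                     regions = list(supramodal_emotion_region = region_sphere(c(4, 4, 4), 2)),
                     amplitudes = c(supramodal_emotion_region = 6),
                     n_subjects = 2)
  bs <- betas_for(ds)
  reg <- ds$truth$regions$supramodal_emotion_region
  acc <- vapply(crossmodal_task_set()[1:2], function(task) {
    map_mean_accuracy(crossmodal_decode(bs[[1]], task, spec), reg)
  }, numeric(1))
  expect_true(all(acc > 0.5))
})
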