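test_that("the canonical HRF peaks near 5 s, samples by ceiling, peak 1", {
  # dense-grid evaluation of the gamma-density difference locates the mode
  spec <- hrf_spec()
  tt <- seq(0, 32, by = 0.001)
  dense <- dgamma(tt, shape = 6, scale = 1) - dgamma(tt, shape = 16, scale = 1) / 6
  expect_equal(tt[which.max(dense)], 5, tolerance = 0.05)
  h_fine <- canonical_hrf(spec, 0.01)
  expect_equal((which.max(h_fine) - 1) * 0.01, 5, tolerance = 0.05)
  expect_length(canonical_hrf(spec, 3), 11)  # ceiling(32 / 3)
  expect_equal(max(canonical_hrf(spec, 3)), 1)
  expect_error(hrf_spec(peak_dispersion = 0), "positive")
})

test_that("drift plus constant absorb slow trends completely", {
  d <- tiny_design()
  ev <- build_design(d, 5)
  dm <- build_trialwise_design(ev[ev$run == 1, ], d$volumes_per_run, d$tr)
  nuis <- dm$values[, !dm$interest, drop = FALSE]
  # a pure drift series lies in the nuisance span
  y <- 3 + 0.5 * cosine_drift(d$volumes_per_run, d$tr)[, 1]
  res <- stats::lm.fit(nuis, y)$residuals
  expect_lt(max(abs(res)), 1e-10)
})

test_that("trial-wise design has one interest regressor per regular trial", {
  d <- tiny_design()
  ev <- build_design(d, 5)
  half <- ev[ev$run == 1 & ev$run_half == "visual", ]
  dm <- build_trialwise_design(half, d$volumes_per_run, d$tr)
  expect_equal(sum(dm$interest), 16)
  expect_equal(nrow(dm$labels), 16)
  full_run <- ev[ev$run == 1, ]
  dm2 <- build_trialwise_design(full_run, d$volumes_per_run, d$tr)
  expect_equal(sum(dm2$interest), 32)
  # interest block is well-conditioned at these ISIs
  Xi <- dm2$values[, dm2$interest]
  expect_lt(kappa(crossprod(Xi), exact = TRUE)^0.5, 10)
  dup <- half
  dup$onset[2] <- dup$onset[1]
  expect_error(build_trialwise_design(dup, d$volumes_per_run, d$tr),
               "design-degenerate")
})

test_that("OLS betas match the explicit normal-equations oracle", {
  d <- tiny_design()
  ev <- build_design(d, 5)
  dm <- build_trialwise_design(ev[ev$run == 1, ], d$volumes_per_run, d$tr)
  set.seed(1)
  Y <- matrix(rnorm(d$volumes_per_run * 5), d$volumes_per_run, 5)
  bs <- estimate_betas(Y, dm)
  X <- dm$values
  oracle <- solve(t(X) %*% X) %*% t(X) %*% Y
  expect_equal(unname(bs$betas), unname(oracle[dm$interest, ]),
               tolerance = 1e-8)
  # permuting voxels permutes beta columns identically
  perm <- c(3, 1, 5, 2, 4)
  bs_p <- estimate_betas(Y[, perm], dm)
  expect_equal(bs_p$betas, bs$betas[, perm], ignore_attr = TRUE)
  # rank-deficient designs are rejected with the offending column named
  dm_bad <- dm
  dm_bad$values <- cbind(dm$values, constant2 = dm$values[, "constant"])
  dm_bad$interest <- c(dm$interest, FALSE)
  expect_error(estimate_betas(Y, dm_bad), "collinear.*constant")
  expect_error(estimate_betas(Y[1:10, ], dm), "match run volumes")
})

test_that("noise-free betas recover the generating amplitudes", {
  ds <- tiny_dataset(seed = 8, regions = voice_region_spec(),
                     amplitudes = c(emotion_voice_region = 5),
                     n_subjects = 2, sigma = 0, ar1 = 0, drift = 0,
                     grid = c(6, 6, 6))
  b <- estimate_trial_betas(ds$subjects[[1]], ds$events)
  A <- trial_amplitudes(ds$truth, ds$events[!ds$events$is_catch, ])
  denom <- max(abs(A))
  expect_lt(max(abs(b$betas - A)) / denom, 1e-6)
})

test_that("nuisance regressors orthogonal to the interest block leave betas unchanged", {
  d <- tiny_design()
  ev <- build_design(d, 5)
  run1 <- ev[ev$run == 1, ]
  dm <- build_trialwise_design(run1, d$volumes_per_run, d$tr)
  set.seed(2)
  Y <- matrix(rnorm(d$volumes_per_run * 4), ncol = 4)
  b0 <- estimate_betas(Y, dm)
  # residualise a random series against the existing design -> orthogonal column
  extra <- stats::lm.fit(dm$values, rnorm(d$volumes_per_run))$residuals
  dm2 <- dm
  dm2$values <- cbind(dm$values, ortho = extra)
  dm2$interest <- c(dm$interest, FALSE)
  b1 <- estimate_betas(Y, dm2)
  expect_equal(b0$betas, b1$betas, tolerance = 1e-8)
})

test_that("the condition design has 12 interest regressors and the stated nuisance set", {
  d <- experiment_design()
  ev <- build_design(d, 5)
  sess1 <- ev[ev$run %in% 1:2, ]
  # a session-1 run has body and voice trials only: 8 of the 12 conditions
  set.seed(3)
  dm1 <- build_condition_design(ev[ev$run == 1, ], d$volumes_per_run, d$tr)
  expect_equal(sum(dm1$interest), 8)
  expect_setequal(attr(dm1, "missing_conditions"),
                  paste("face", c("anger", "happy", "neutral", "fear"), sep = "_"))
  # with all three categories present the full 12 appear
  both <- rbind(ev[ev$run == 1, ], transform(ev[ev$run == 7, ], run = 1))
  both <- both[order(both$onset), ]
  both <- both[!duplicated(round(both$onset, 3)), ]
  dm12 <- build_condition_design(both, d$volumes_per_run, d$tr)
  expect_equal(sum(dm12$interest), 12)
  expect_length(attr(dm12, "missing_conditions"), 0)
  # nuisance: block start + catch + 6 motion + drift set + constant
  n_drift <- ncol(cosine_drift(d$volumes_per_run, d$tr))
  expect_equal(sum(!dm12$interest), 1 + 1 + 6 + n_drift + 1)
})

test_that("condition means of trial betas equal condition betas on noiseless data", {
  ds <- tiny_dataset(seed = 9, regions = voice_region_spec(),
                     amplitudes = c(emotion_voice_region = 5),
                     n_subjects = 2, sigma = 0, ar1 = 0, drift = 0,
                     grid = c(6, 6, 6))
  trial <- estimate_trial_betas(ds$subjects[[1]], ds$events)
  set.seed(4)
  cond <- estimate_condition_betas(ds$subjects[[1]], ds$events)
  key <- paste(trial$labels$stimulus_type, trial$labels$emotion, sep = "_")
  for (cn in rownames(cond$betas)) {
    expect_equal(colMeans(trial$betas[key == cn, , drop = FALSE]),
                 cond$betas[cn, ], tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("beta recovery error grows with noise sigma", {
  d <- tiny_design(1L)
  sigmas <- c(0, 0.5, 1, 2)
  cfg <- ground_truth_config(grid_shape = c(6, 6, 6), regions = voice_region_spec(),
                             amplitudes = c(emotion_voice_region = 5))
  truth <- simulate_patterns(cfg, 2)
  rmse <- matrix(NA_real_, 20, length(sigmas))
  for (s in 1:20) {
    ev <- build_design(d, s)
    ev1 <- ev[ev$run == 1, ]
    A <- trial_amplitudes(truth, ev1[!ev1$is_catch, ])
    for (k in seq_along(sigmas)) {
      run <- simulate_run(ev1, truth, noise_model(sigmas[k], 0.3, 0.5), d,
                          seed = 1000 * s + k)
      dm <- build_trialwise_design(ev1, d$volumes_per_run, d$tr)
      b <- estimate_betas(run, dm)
      rmse[s, k] <- sqrt(mean((b$betas - A)^2))
    }
  }
  expect_true(all(diff(colMeans(rmse)) > 0))
})

test_that("smoothing preserves mass, hits the requested FWHM, and 0 is identity", {
  vol <- array(0, c(15, 15, 15))
  vol[8, 8, 8] <- 1
  expect_identical(smooth_volume(vol, 0), vol)
  sm <- smooth_volume(vol, 6, voxel_size_mm = 2)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  # measure the empirical FWHM along an axis through the peak (voxel units)
  prof <- sm[, 8, 8]
  half <- max(prof) / 2
  above <- range(which(prof >= half))
  # linear interpolation at the half-maximum crossings
  lo <- above[1] - (prof[above[1]] - half) / (prof[above[1]] - prof[above[1] - 1])
  hi <- above[2] + (prof[above[2]] - half) / (prof[above[2]] - prof[above[2] + 1])
  expect_equal((hi - lo) * 2, 6, tolerance = 0.5)  # mm at 2 mm voxels
  # anisotropic voxels get per-axis sigmas
  sm2 <- smooth_volume(vol, 6, voxel_size_mm = c(2, 4, 2))
  expect_gt(sd(sm2[8, , 8] - sm2[, 8, 8]), 0)
})

test_that("the repeated-measures ANOVA matches a sums-of-squares oracle", {
  # 3 subjects x 12 conditions x 2 voxels, hand-checkable
  set.seed(11)
  labels <- expand.grid(stimulus_type = c("face", "body", "voice"),
                        emotion = c("anger", "happy", "neutral", "fear"),
                        stringsAsFactors = FALSE)
  mk <- function(shift) {
    b <- matrix(rnorm(12 * 2), 12, 2)
    b[labels$stimulus_type == "voice", 1] <- b[labels$stimulus_type == "voice", 1] + shift
    structure(list(betas = b, labels = labels), class = "condition_beta_set")
  }
  cb <- list(mk(2), mk(2.5), mk(1.5))
  res <- anova_factor_map(cb, "modality")
  # oracle via stats::aov on the long data for voxel 1
  long <- do.call(rbind, lapply(seq_along(cb), function(s) {
    agg <- tapply(cb[[s]]$betas[, 1], labels$stimulus_type, mean)
    data.frame(subject = s, level = names(agg), y = as.numeric(agg))
  }))
  fit <- summary(stats::aov(y ~ level + Error(factor(subject)/level), data = long))
  F_oracle <- fit[["Error: factor(subject):level"]][[1]]["level", "F value"]
  expect_equal(res$F[1], F_oracle, tolerance = 1e-8)
  # identical level means for all levels -> F ~ 0, p ~ 1
  flat <- lapply(1:3, function(s) {
    b <- matrix(rep(rnorm(2), each = 12), 12, 2)
    structure(list(betas = b, labels = labels), class = "condition_beta_set")
  })
  res0 <- anova_factor_map(flat, "emotion")
  expect_equal(res0$F, c(0, 0))
  expect_equal(res0$p, c(1, 1))
  expect_error(anova_factor_map(cb[1], "modality"), "2 subjects")
})
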