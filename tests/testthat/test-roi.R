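test_that("the packaged ROI peak table has the published coordinates", {
  tab <- roi_table()
  expect_setequal(unique(tab$roi),
                  c("FFA", "EV", "EBA", "A1", "MPFC", "pSTS", "Amygdala"))
  ffa <- tab[tab$roi == "FFA", ]
  expect_equal(c(ffa$x, ffa$y, ffa$z), c(39, -52, -26))
  # bilateral regions carry one row per hemisphere
  expect_equal(nrow(tab[tab$roi == "A1", ]), 2)
  expect_equal(nrow(tab[tab$roi == "Amygdala", ]), 2)
})

test_that("spherical ROIs honour radius, affine and mask", {
  grid <- c(13, 13, 13)
  aff <- grid_affine(grid, voxel_size_mm = 2)
  # radius 0 -> the single nearest voxel to the mm centre
  centre_mm <- drop(emodecode:::vox_to_mm(c(7, 7, 7), aff))
  expect_equal(sphere_roi(centre_mm + 0.4, 0, grid, aff),
               emodecode:::vox_to_index(c(7, 7, 7), grid))
  # fully interior sphere has exactly the sphere_offsets voxel count
  roi <- sphere_roi(centre_mm, 5, grid, aff)
  expect_length(roi, nrow(sphere_offsets(5)))
  # centre outside the grid errors with the ROI named
  expect_error(sphere_roi(c(500, 0, 0), 5, grid, aff, name = "FFA"), "FFA")
  # empty mask intersection errors with the ROI named
  mask <- array(FALSE, grid)
  expect_error(sphere_roi(centre_mm, 1, grid, aff, brain_mask = mask,
                          name = "pSTS"), "pSTS")
  # bilateral union through roi_masks
  tab <- data.frame(roi = c("A1", "A1"), part = c("L", "R"),
                    size_voxels = 1, x = c(-6, 6), y = 0, z = 0)
  rois <- roi_masks(tab, grid, aff, radius_voxels = 1)
  expect_length(rois, 1)
  expect_length(rois$A1, 2 * nrow(sphere_offsets(1)))
})

test_that("condition means cover the 16 cells with correct SE and linearity", {
  b <- tiny_null_betas()[[1]]
  roi <- which(b$brain_mask)[1:10]
  cm <- condition_means(b, roi)
  expect_length(cm, 16)
  expect_identical(names(cm), roi_condition_order())
  # constant data -> all 16 means equal the constant, group SE 0
  bc <- b
  bc$betas[] <- 3
  cmc <- condition_means(bc, roi)
  expect_equal(unname(cmc), rep(3, 16))
  # linearity
  b2 <- b
  b2$betas <- 2 * b$betas
  expect_equal(condition_means(b2, roi), 2 * cm)
  # group SE equals sd / sqrt(n) on a 3-subject toy
  bl <- tiny_null_betas()
  g <- group_condition_means(bl, roi)
  per <- vapply(bl, function(x) condition_means(x, roi)[1], numeric(1))
  expect_equal(g$se[1], sd(per) / sqrt(3))
  expect_equal(g$mean[1], mean(per))
  # a missing cell is flagged, not zero-filled
  b_miss <- b
  keep <- !(b$labels$stimulus_type == "face" & b$labels$emotion == "fear")
  b_miss$betas <- b$betas[keep, ]
  b_miss$labels <- b$labels[keep, ]
  cm_miss <- condition_means(b_miss, roi)
  expect_true(is.na(cm_miss["face_fear"]))
  expect_equal(attr(cm_miss, "empty_conditions"), "face_fear")
})

test_that("RDMs are 1 - Pearson r with the required structure", {
  set.seed(6)
  P <- matrix(rnorm(16 * 30), 16, dimnames = list(roi_condition_order(), NULL))
  D <- compute_rdm(P)
  expect_equal(dim(D), c(16, 16))
  expect_identical(attr(D, "condition_order"), roi_condition_order())
  # oracle: direct covariance-formula correlation, pairwise
  for (i in c(1, 7, 16)) for (j in c(2, 9)) {
    num <- mean(P[i, ] * P[j, ]) - mean(P[i, ]) * mean(P[j, ])
    den <- sqrt((mean(P[i, ]^2) - mean(P[i, ])^2) * (mean(P[j, ]^2) - mean(P[j, ])^2))
    expect_equal(D[i, j], 1 - num / den, tolerance = 1e-10)
  }
  expect_equal(unname(diag(D)), rep(0, 16))
  expect_equal(D, t(D), ignore_attr = TRUE)
  expect_true(all(D >= 0 & D <= 2))
  # self vs negation
  Q <- rbind(P[1, ], -P[1, ])
  rownames(Q) <- c("a", "b")
  DQ <- compute_rdm(Q)
  expect_equal(DQ["a", "b"], 2)
  expect_error(compute_rdm(P[, 1, drop = FALSE]), "at least 2 voxels")
  Pz <- P
  Pz[3, ] <- 1
  expect_warning(compute_rdm(Pz), "zero-variance")
})

test_that("modality-dominated data give between-block > within-block dissimilarity", {
  ds <- tiny_dataset(seed = 31,
                     regions = list(modality_region = region_sphere(c(4, 4, 4), 2)),
                     amplitudes = c(modality_region = 8), n_subjects = 2)
  bl <- betas_for(ds)
  roi <- ds$truth$regions$modality_region
  rdms <- lapply(bl, function(b) compute_rdm(condition_patterns(b, roi)))
  ctr <- rdm_block_contrast(average_rdm(rdms))
  expect_gt(ctr["between"], ctr["within"])
})

test_that("the ROI decoding report has the 10 tasks with table-wide FDR", {
  fx <- tiny_voice_betas()
  region <- fx$truth$regions$emotion_voice_region
  far <- setdiff(which(fx$truth$brain_mask),
                 unlist(lapply(fx$truth$regions, identity)))
  rois <- list(signal_roi = region, control_roi = far[1:30])
  rep <- roi_decode(fx$betas, rois)
  expect_equal(nrow(rep), 2 * 10)
  expect_setequal(unique(rep$task), names(roi_default_tasks()))
  # FDR across the grid equals bh_fdr on the flattened p-vector
  expect_equal(rep$p_fdr, bh_fdr(rep$p)$p_adjusted)
  # voice-emotion signal detected in the signal ROI, not in the control ROI
  p_sig <- rep$p[rep$roi == "signal_roi" & rep$task == "emotion_voice_s1"]
  p_ctl <- rep$p[rep$roi == "control_roi" & rep$task == "emotion_voice_s1"]
  expect_lt(p_sig, 0.05)
  expect_gt(p_ctl, 0.05)
  acc_sig <- rep$accuracy[rep$roi == "signal_roi" & rep$task == "emotion_voice_s1"]
  expect_gt(acc_sig, 0.4)
  # cross-modal tasks give no FDR-significant generalization without
  # supramodal structure (single-split accuracies are individually noisy:
  # same-emotion test trials share one pattern, so per-subject accuracy has
  # few effective degrees of freedom -- the group test absorbs that)
  cm <- rep[grepl("_to_", rep$task), ]
  expect_false(any(cm$significant))
  expect_lt(abs(mean(cm$accuracy) - 0.25), 0.12)
})

test_that("ROI decoding on one sphere equals the searchlight at its centre", {
  fx <- tiny_voice_betas()
  b <- fx$betas[[1]]
  spec <- searchlight_spec(2, 1)
  grid <- b$grid_shape
  centre <- c(4, 4, 4)
  centre_idx <- emodecode:::vox_to_index(centre, grid)
  map <- searchlight_decode(b, task_emotion_within("voice"), spec)
  # the ROI = that centre's sphere-mask intersection
  off <- sphere_offsets(2)
  q <- sweep(off, 2, centre, "+")
  ok <- apply(q >= 1 & sweep(q, 2, grid, "<="), 1, all)
  roi <- sort(emodecode:::vox_to_index(q[ok, , drop = FALSE], grid))
  acc <- emodecode:::roi_task_accuracy(
    b$betas[, match(roi, which(b$brain_mask)), drop = FALSE],
    b$labels, task_emotion_within("voice"))
  expect_equal(acc, map$values[match(centre_idx, map$mask_idx)],
               tolerance = 1e-12)
})
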