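acc_maps <- function(M, chance, grid = c(5, 5, 2)) {
  lapply(seq_len(nrow(M)), function(s) {
    accuracy_map(M[s, ], grid, chance)
  })
}

test_that("the group t-test matches the textbook formula and stats::t.test", {
  vals <- c(0.30, 0.35, 0.25, 0.30)
  maps <- acc_maps(matrix(rep(vals, 3), 4), chance = 0.25, grid = c(3, 1, 1))
  gm <- ttest_vs_chance(maps)
  t_hand <- (mean(vals) - 0.25) / (sd(vals) / sqrt(4))
  expect_equal(gm$t[1], t_hand, tolerance = 1e-12)
  ref <- t.test(vals, mu = 0.25, alternative = "greater")
  expect_equal(gm$t[2], unname(ref$statistic))
  expect_equal(gm$p[3], ref$p.value)
  # all subjects exactly at chance -> t = 0, p = 0.5
  null_maps <- acc_maps(matrix(0.25, 4, 3), 0.25, c(3, 1, 1))
  gm0 <- ttest_vs_chance(null_maps)
  expect_equal(gm0$t, rep(0, 3))
  expect_equal(gm0$p, rep(0.5, 3))
  # shifting every subject up increases t monotonically
  gm_up <- ttest_vs_chance(acc_maps(matrix(rep(vals + 0.05, 3), 4), 0.25,
                                    c(3, 1, 1)))
  expect_true(all(gm_up$t > gm$t))
  # voxels defined in fewer than 2 subjects are undefined
  M <- matrix(0.3, 3, 2)
  M[2:3, 2] <- NA
  gm_na <- ttest_vs_chance(acc_maps(M, 0.25, c(2, 1, 1)))
  expect_true(is.na(gm_na$t[2]))
})

test_that("Bonferroni FWE reduces to alpha at m = 1 and nests in uncorrected", {
  maps <- acc_maps(matrix(c(0.5, 0.9, 0.45, 0.8, 0.55, 0.85), 3, byrow = TRUE),
                   0.5, c(2, 1, 1))
  gm <- ttest_vs_chance(maps)
  one <- gm
  one$p <- gm$p[2]
  one$t <- gm$t[2]
  r1 <- fwe_correct(one, alpha = 0.05)
  expect_equal(r1$threshold, 0.05)
  rall <- fwe_correct(gm, alpha = 0.05)
  expect_true(all(gm$p[rall$reject] <= 0.05))
  expect_error(fwe_correct(gm, method = "max_stat_permutation"), "perm_t")
  # max-statistic method thresholds at the permutation max-t quantile
  perm <- lapply(1:40, function(i) rnorm(2))
  rmax <- fwe_correct(gm, method = "max_stat_permutation", perm_t = perm)
  expect_true(all(gm$t[rmax$reject] > rmax$threshold))
})

test_that("Bonferroni controls the family-wise error under a uniform null", {
  set.seed(77)
  m <- 50
  fwe_hits <- vapply(1:500, function(i) {
    p <- runif(m)
    sm <- list(p = p, t = qnorm(1 - p))
    class(sm) <- "group_stat_map"
    any(fwe_correct(sm, 0.05)$reject)
  }, logical(1))
  # binomial 3-sigma band around the nominal level
  expect_lt(mean(fwe_hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("BH-FDR matches the exhaustive step-up oracle and is order-invariant", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$reject))
  expect_false(any(bh_fdr(rep(1, 6), 0.05)$reject))
  set.seed(8)
  for (i in 1:100) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    r <- bh_fdr(p, 0.05)
    expect_identical(r$reject, oracle_bh_reject(p, 0.05))
    # adjusted p are monotone in p
    expect_true(all(diff(r$p_adjusted[order(p)]) >= -1e-12))
    sh <- sample(length(p))
    expect_identical(bh_fdr(p[sh], 0.05)$reject, r$reject[sh])
  }
})

make_stat_map <- function(p, grid, mask_idx = seq_along(p), t = qnorm(1 - p)) {
  structure(list(p = p, t = t, df = rep(7, length(p)), mask_idx = mask_idx,
                 grid_shape = grid, affine = grid_affine(grid)),
            class = "group_stat_map")
}

test_that("cluster-extent thresholding removes small components and keeps blobs", {
  grid <- c(10, 10, 10)
  p <- rep(1, 1000)
  # an isolated voxel dies at k = 25
  p[emodecode:::vox_to_index(c(5, 5, 5), grid)] <- 1e-5
  cl <- cluster_threshold(make_stat_map(p, grid), 0.001, 25)
  expect_equal(nrow(cl$table), 0)
  # a 3 x 3 x 3 blob of 27 voxels survives as one cluster
  blob <- as.matrix(expand.grid(4:6, 4:6, 4:6))
  p2 <- rep(1, 1000)
  p2[emodecode:::vox_to_index(blob, grid)] <- 1e-5
  cl2 <- cluster_threshold(make_stat_map(p2, grid), 0.001, 25)
  expect_equal(nrow(cl2$table), 1)
  expect_equal(cl2$table$size, 27)
  expect_equal(sum(cl2$labels == 1), 27)
  # peak coordinates are reported in mm through the affine
  expect_true(all(c("x", "y", "z") %in% names(cl2$table)))
})

test_that("cluster labels agree with a flood-fill oracle on random maps", {
  set.seed(12)
  grid <- c(8, 8, 8)
  for (i in 1:50) {
    conn <- sample(c(6, 26), 1)
    p <- ifelse(runif(prod(grid)) < 0.25, 1e-5, 1)
    sm <- make_stat_map(p, grid)
    cl <- cluster_threshold(sm, 0.001, 1, connectivity = conn)
    supra <- which(p < 0.001)
    oracle <- oracle_flood_fill(supra, grid, conn)
    expect_true(same_partition(cl$labels[supra], oracle))
  }
})

test_that("cluster labelling is invariant under grid translation", {
  grid <- c(12, 12, 12)
  blob <- as.matrix(expand.grid(3:5, 3:5, 3:5))
  for (shift in list(c(0, 0, 0), c(4, 2, 5))) {
    p <- rep(1, prod(grid))
    p[emodecode:::vox_to_index(sweep(blob, 2, shift, "+"), grid)] <- 1e-5
    cl <- cluster_threshold(make_stat_map(p, grid), 0.001, 10)
    expect_equal(cl$table$size, 27)
  }
})

test_that("type-I rate of the t-vs-chance test is nominal under the null", {
  set.seed(99)
  n_sub <- 8
  V <- 40
  rates <- vapply(1:500, function(i) {
    M <- matrix(0.25 + rnorm(n_sub * V, sd = 0.03), n_sub, V)
    gm <- ttest_vs_chance(acc_maps(M, 0.25, c(V, 1, 1)))
    mean(gm$p <= 0.05)
  }, numeric(1))
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.05), 4 * se + 1e-3)
})

test_that("permutation label sets shuffle within run and keep balance", {
  b <- tiny_null_betas()[[1]]
  task <- task_emotion_all()
  labels <- b$labels[task$filter(b$labels), ]
  sch <- permutation_scheme(labels, task, n_permutations = 10, seed = 4)
  y <- task$label_fun(labels)
  for (p in 1:10) {
    perm <- sch$label_sets[p, ]
    expect_identical(table(labels$run, perm, dnn = NULL),
                     table(labels$run, y, dnn = NULL))
  }
  # at least some permutations actually move labels
  expect_true(any(apply(sch$label_sets, 1, function(s) !all(s == y))))
})

test_that("the permutation group test is null-centred and tracks true signal", {
  fx <- tiny_voice_betas()
  spec <- searchlight_spec(2, 5)
  task <- task_emotion_within("voice")
  labels <- fx$betas[[1]]$labels[task$filter(fx$betas[[1]]$labels), ]
  # the identity 'permutation' gives a paired t of exactly 0 everywhere
  sch_id <- permutation_scheme(labels, task, n_permutations = 1, seed = 1)
  sch_id$label_sets[1, ] <- task$label_fun(labels)
  res_id <- permutation_group_test(fx$betas, task, spec, sch_id)
  expect_true(all(res_id$t_avg == 0, na.rm = TRUE))
  # real permutations: averaged t elevated in the region, concordant with
  # the direct t-vs-chance map
  sch <- permutation_scheme(labels, task, n_permutations = 4, seed = 2)
  res <- permutation_group_test(fx$betas, task, spec, sch,
                                true_maps = res_id$true_maps)
  direct <- ttest_vs_chance(res_id$true_maps)
  ok <- !is.na(res$t_avg) & !is.na(direct$t)
  expect_gt(cor(res$t_avg[ok], direct$t[ok], method = "spearman"), 0)
  region <- fx$truth$regions$emotion_voice_region
  in_reg <- fx$betas[[1]]$brain_mask[region]
  # with few subjects some voxels have zero-variance paired diffs (t = Inf);
  # compare the finite bulk
  reg_t <- res$t_avg[match(region, which(fx$truth$brain_mask))]
  expect_gt(mean(reg_t[is.finite(reg_t)]),
            mean(res$t_avg[is.finite(res$t_avg)]))
})
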