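test_that("feature extraction flattens and round-trips exactly", {
  d <- c(10, 10, 4)
  mask <- volume_grid(array(as.numeric(array(seq_len(prod(d)), d) %% 4 == 0), d),
                      c(1, 1, 1))
  n_vox <- sum(mask$values)
  doses <- lapply(1:10, function(i) volume_grid(array(i * 1.0, d), c(1, 1, 1)))
  names(doses) <- sprintf("p%02d", 1:10)
  fm <- extract_features(doses, mask)
  expect_equal(dim(fm$values), c(10, n_vox))
  expect_true(all(fm$values[7, ] == 7))
  # column -> 3D -> column round trip
  map <- voxels_to_map(fm$values[3, ], fm)
  expect_identical(as.numeric(map$values)[fm$voxel_index], fm$values[3, ])
  expect_identical(sum(map$values != 0), sum(fm$values[3, ] != 0))
  bad <- volume_grid(array(1, c(5, 5, 5)), c(1, 1, 1))
  expect_error(extract_features(list(bad), mask), "does not match")
})

test_that("standardization is exact on the training rows only", {
  x <- matrix(c(1, 2, 3, 10), ncol = 1)
  st <- standardize(x, 1:3)
  expect_equal(st$x[1:3, 1], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  # test row transformed with training parameters
  expect_equal(st$x[4, 1], (10 - 2) / sqrt(2 / 3), tolerance = 1e-12)

  xc <- cbind(a = c(5, 5, 5, 5), b = c(1, 2, 3, 4))
  st <- standardize(xc, 1:4)
  expect_true(st$params$zero_variance[["a"]])
  expect_true(all(st$x[, "a"] == 0))

  # a test row equal to the training mean maps to all zeros
  x2 <- rbind(matrix(rnorm(30), 10, 3), 0)
  x2[11, ] <- colMeans(x2[1:10, ])
  st <- standardize(x2, 1:10)
  expect_equal(unname(st$x[11, ]), c(0, 0, 0), tolerance = 1e-10)
})

test_that("split_cohort is stratified, deterministic, and sized 80/20", {
  ids <- sprintf("p%03d", 1:100)
  y <- setNames(rep(c(0, 1), each = 50), ids)
  sp <- split_cohort(ids, y, 0.2, seed = 4)
  expect_length(sp$test, 20)
  expect_length(sp$train, 80)
  expect_equal(sum(y[sp$test]), 10)  # stratified
  sp2 <- split_cohort(ids, y, 0.2, seed = 4)
  expect_identical(sp, sp2)
})

test_that("ridge tuning handles limits and separable data", {
  set.seed(8)
  # heavy penalty limit: coefficients shrink to ~0, predictions ~constant
  x <- matrix(rnorm(400), 100, 4)
  y <- rbinom(100, 1, 0.5)
  m <- fit_ridge(x, y, 1e9, penalty_grid())
  expect_lt(max(abs(m$beta)), 1e-4)
  expect_equal(auc_roc(rep(0.5, 100), y), 0.5)

  # shrinkage monotone across a sweep
  norms <- vapply(10^seq(-2, 4, length.out = 10), function(l) {
    sqrt(sum(fit_ridge(x, y, l, penalty_grid())$beta^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))

  # two separated Gaussian clusters: CV AUC >= 0.95
  xs <- rbind(matrix(rnorm(200, -2), 50, 4), matrix(rnorm(200, 2), 50, 4))
  ys <- rep(c(0, 1), each = 50)
  tn <- tune_ridge(xs, ys, seed = 2)
  expect_gte(tn$cv_auc_mean, 0.95)
  tn2 <- tune_ridge(xs, ys, seed = 2)
  expect_identical(tn$lambda, tn2$lambda)
  expect_error(tune_ridge(xs, rep(1, 100), seed = 1), "both classes")
})

test_that("the voxel model recovers a planted signal and respects support", {
  co <- smoke_cohort(n = 120, seed = 33, volumes = FALSE)
  fm <- truth_feature_matrix(co, "pc")
  idx <- partition_indices(co$partition, "pc_superior")
  cols <- match(idx, fm$voxel_index)
  # deterministic outcome: indicator(planted-region mean dose > median)
  sig <- rowMeans(fm$values[, cols])
  y <- setNames(as.numeric(sig > median(sig)), fm$patient_ids)
  vm <- fit_voxel_model(fm, y, seed = 3)
  expect_gte(vm$report$test_auc, 0.8)
  nz <- which(vm$coefficient_map$values != 0)
  ref_mask_idx <- fm$voxel_index
  expect_true(all(nz %in% ref_mask_idx))
  expect_true(all(vm$report[c("cv_auc_mean", "train_auc", "test_auc")] >= 0))

  # label-independent outcomes: test AUC near chance
  y0 <- setNames(with_seed(9, sample(rep(c(0, 1), 60))), fm$patient_ids)
  vm0 <- fit_voxel_model(fm, y0, seed = 5)
  expect_gte(vm0$report$test_auc, 0.2)
  expect_lte(vm0$report$test_auc, 0.8)
})

test_that("flip augmentation doubles training rows, not the test set", {
  co <- smoke_cohort(n = 40, seed = 1, volumes = FALSE)
  y <- setNames(vapply(co$cases, function(c) c$outcome, numeric(1)),
                vapply(co$cases, function(c) c$id, character(1)))
  fm <- truth_feature_matrix(co, "pc")
  fmf <- truth_feature_matrix(co, "pc", flip = TRUE)
  vm <- fit_voxel_model(fm, y, fm_flipped = fmf, seed = 2)
  expect_equal(vm$report$n_rows_fit, 2 * vm$report$n_train)
  expect_equal(vm$report$n_train + vm$report$n_test, 40)
  # the same patients make up train and test regardless of augmentation
  vm0 <- fit_voxel_model(fm, y, seed = 2)
  expect_identical(sort(vm$split$test), sort(vm0$split$test))
})

test_that("importance_summary computes subregion shares", {
  co <- smoke_cohort(n = 10, seed = 44, volumes = FALSE)
  p <- co$partition
  ref_mask <- co$reference$pc_mask
  # uniform coefficients: shares proportional to PC subregion voxel counts
  arr <- array(0, dim(ref_mask$values))
  arr[p$labels > 0 & p$labels <= 6] <- 1
  m <- volume_grid(arr, ref_mask$spacing)
  sh <- importance_summary(m, p, q = 100)
  pc_counts <- p$counts[1:6]
  expect_equal(unname(sh[1:6]), unname(pc_counts / sum(pc_counts)),
               tolerance = 1e-12)
  # all top voxels planted in one subregion
  arr2 <- array(0, dim(ref_mask$values))
  arr2[p$labels == 3] <- 5
  arr2[p$labels > 0 & p$labels != 3] <- 0.01
  sh2 <- importance_summary(volume_grid(arr2, ref_mask$spacing), p, q = 5)
  expect_equal(unname(sh2["pc_middle_midline"]), 1.0)
  expect_equal(sum(sh2), 1.0)
  expect_error(importance_summary(m, p, q = 0), "q must be")
})
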