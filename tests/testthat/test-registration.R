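test_that("warping through fields honors its contract", {
  ref <- smoke_ref()
  d <- smoke_shape
  zero <- deformation_field(array(0, c(d, 3)), smoke_spacing)
  out <- warp(ref$pc_mask, zero, "nearest")
  expect_identical(out$values, ref$pc_mask$values)

  const <- volume_grid(array(42, d), smoke_spacing)
  set.seed(11)
  fld <- deformation_field(
    array(rnorm(prod(d) * 3, sd = 2), c(d, 3)), smoke_spacing)
  w <- warp(const, fld, "linear")
  inb <- w$values[w$values != 0]
  expect_true(all(abs(inb - 42) < 1e-9))
})

test_that("identity registration is (near) exact", {
  ref <- smoke_ref()
  r <- register(ref$pc_mask, ref$pc_mask)
  expect_gte(r$qc$dice_after, 0.99)
  expect_lte(mean(field_norms <- sqrt(rowSums(
    matrix(r$field$displacement, ncol = 3)^2))), 0.5)
  expect_true(r$qc$pass_flag)
})

test_that("a pure 5 mm translation is recovered by the rigid stage", {
  ref <- smoke_ref()
  m <- ref$larynx_mask
  shifted <- m
  shifted$values <- array(0, dim(m$values))
  # translate by 4 voxels in y at 1.27 mm (~5 mm)
  shifted$values[, 5:dim(m$values)[2], ] <- m$values[, 1:(dim(m$values)[2] - 4), ]
  r <- register(shifted, m)
  expect_gte(r$qc$dice_after, 0.95)
  expect_gte(r$qc$dice_after, r$qc$dice_before)
})

test_that("registration improves Dice on synthetic cases and self-checks", {
  ref <- smoke_ref()
  for (s in 1:5) {
    cs <- sample_patient(ref, seed = 700 + s)
    r <- register(cs$pc_mask, ref$pc_mask)
    expect_gte(r$qc$dice_after, r$qc$dice_before)
    # warp consistency: Dice of the warped mask equals the reported QC value
    dw <- dice(warp(cs$pc_mask, r$field, "nearest"), ref$pc_mask)
    expect_equal(dw, r$qc$dice_after, tolerance = 1e-12)
  }
  expect_error(register(box_mask(c(20, 20, 20), c(5, 5, 5), c(5, 5, 5)),
                        box_mask(c(20, 20, 20), c(6, 6, 6), c(6, 6, 6))),
               "single-voxel")
})

test_that("dose mass is approximately preserved by normalization", {
  ref <- smoke_ref()
  for (s in 1:4) {
    cs <- sample_patient(ref, seed = 800 + s)
    r <- register(cs$pc_mask, ref$pc_mask)
    wd <- warp(cs$dose, r$field, "linear")
    before <- mean_dose(cs$dose, cs$pc_mask)
    after <- mean_dose(wd, ref$pc_mask)
    expect_lt(abs(after - before) / before, 0.15)
  }
})

test_that("flip-augmented normalization mirrors the warped dose", {
  co <- smoke_cohort(n = 12, seed = 21, volumes = FALSE)
  np <- normalize_cohort(co, "pc", "truth", augment_flip = TRUE)
  expect_length(np$flipped_doses, 12)
  id <- names(np$warped_doses)[1]
  expect_identical(np$flipped_doses[[id]]$values,
                   vg_flip_lr(np$warped_doses[[id]])$values)
  # lean feature path agrees with the full-grid truth normalization
  fm <- truth_feature_matrix(co, "pc")
  idx <- fm$voxel_index
  expect_equal(unname(fm$values[1, ]),
               unname(as.numeric(np$warped_doses[[id]]$values)[idx]),
               tolerance = 1e-9)
})
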