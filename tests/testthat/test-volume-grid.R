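test_that("volume_grid validates its invariants", {
  expect_error(volume_grid(array(1, c(4, 4, 4)), c(1, -1, 1)), "spacing")
  expect_error(volume_grid(array(c(NA, rep(1, 63)), c(4, 4, 4)), c(1, 1, 1)),
               "finite")
  expect_error(assert_mask(volume_grid(array(0.5, c(2, 2, 2)), c(1, 1, 1))),
               "0/1")
  expect_error(assert_mask(volume_grid(array(0, c(2, 2, 2)), c(1, 1, 1))),
               "empty")
})

test_that("resampling preserves constants and reproduces linear ramps", {
  v <- volume_grid(array(3.5, c(8, 8, 8)), c(2.54, 2.54, 2))
  out <- vg_resample(v, c(1.27, 1.27, 1))
  expect_true(all(out$values == 3.5))
  # voxel counts roughly double when halving the spacing
  expect_equal(dim(out$values), c(15, 15, 15))

  ramp <- volume_grid(outer(rep(1, 6), outer(rep(1, 6), 0:9 * 2)) |>
                        array(c(6, 6, 10)), c(2, 2, 2))
  out <- vg_resample(ramp, c(2, 2, 1), mode = "linear")
  # new z samples at 0,1,...: ramp value = z_mm (slope 1/mm along z)
  k <- seq_len(dim(out$values)[3]) - 1
  expect_equal(out$values[3, 3, ], k * 1, tolerance = 1e-12)

  m <- box_mask(c(8, 8, 8), c(3, 3, 3), c(6, 6, 6))
  out <- vg_resample(m, c(0.5, 0.5, 0.5), mode = "nearest")
  expect_true(all(out$values %in% c(0, 1)))
  expect_error(vg_resample(v, c(0, 1, 1)), "spacing")
})

test_that("crop_to_organ follows the stated margin arithmetic", {
  d <- c(40, 40, 40)
  m <- box_mask(d, c(11, 11, 11), c(21, 21, 21), spacing = c(1.27, 1.27, 1))
  v <- volume_grid(array(seq_len(prod(d)), d), c(1.27, 1.27, 1))
  out <- vg_crop(v, m, margin = 4)
  # ceil(4/1.27)=4 voxels in x/y, ceil(4/1)=4 in z
  expect_equal(dim(out$values), c(11 + 8, 11 + 8, 11 + 8))
  expect_equal(out$origin, c(6 * 1.27, 6 * 1.27, 6 * 1))

  tight <- vg_crop(v, m, margin = 0)
  expect_equal(dim(tight$values), c(11, 11, 11))

  edge <- box_mask(d, c(1, 1, 1), c(5, 5, 5), spacing = c(1.27, 1.27, 1))
  out <- vg_crop(v, edge, margin = 4)       # clipped at the volume edge
  expect_equal(out$origin, c(0, 0, 0))
  expect_error(vg_crop(v, box_mask(d, c(1, 1, 1), c(1, 1, 1),
                                   spacing = c(1, 1, 1))), "share a grid")
})

test_that("dice matches its analytic cases and is symmetric", {
  d <- c(20, 20, 20)
  a <- box_mask(d, c(1, 1, 1), c(10, 10, 10))
  expect_equal(dice(a, a), 1.0)
  b <- box_mask(d, c(11, 11, 11), c(20, 20, 20))
  expect_equal(dice(a, b), 0.0)
  # two 10x10x10 boxes overlapping in a 5x10x10 slab
  c1 <- box_mask(d, c(1, 1, 1), c(10, 10, 10))
  c2 <- box_mask(d, c(6, 1, 1), c(15, 10, 10))
  expect_equal(dice(c1, c2), 0.5)
  expect_error(dice(box_mask(d, c(1, 1, 1), c(1, 1, 1)) |>
                      (\(m) { m$values[] <- 0; m })(),
                    box_mask(d, c(1, 1, 1), c(1, 1, 1)) |>
                      (\(m) { m$values[] <- 0; m })()), "undefined")
  set.seed(42)
  for (i in 1:25) {
    m1 <- random_mask(c(8, 8, 8)); m2 <- random_mask(c(8, 8, 8))
    if (sum(m1$values) + sum(m2$values) == 0) next
    expect_identical(dice(m1, m2), dice(m2, m1))
  }
})

test_that("left-right flip is an involution and mirrors centroids", {
  set.seed(3)
  v <- random_dose(c(9, 7, 5))
  expect_identical(vg_flip_lr(vg_flip_lr(v))$values, v$values)

  # a left-lateralized blob's dose centroid mirrors about the grid midline
  d <- c(21, 11, 11)
  a <- arrayInd(seq_len(prod(d)), d) - 1L
  g <- exp(-((a[, 1] - 4)^2 + (a[, 2] - 5)^2 + (a[, 3] - 5)^2) / 8)
  v <- volume_grid(array(g, d), c(1, 1, 1))
  cx <- function(vol) {
    w <- as.numeric(vol$values)
    sum(a[, 1] * w) / sum(w)
  }
  mid <- (d[1] - 1) / 2
  expect_equal(cx(vg_flip_lr(v)) - mid, -(cx(v) - mid), tolerance = 1e-10)

  ref <- smoke_ref()
  expect_gte(dice(vg_flip_lr(ref$pc_mask), ref$pc_mask), 0.95)
})

test_that("NIfTI round trip preserves volumes and deformation fields", {
  set.seed(9)
  v <- random_dose(c(11, 13, 7), spacing = c(1.27, 1.27, 1))
  v$origin <- c(-5, 2.5, 10)
  for (ext in c(".nii", ".nii.gz")) {
    path <- tempfile(fileext = ext)
    write_nifti(v, path)
    back <- read_nifti(path)
    expect_equal(back$values, v$values)
    expect_equal(back$spacing, v$spacing, tolerance = 1e-6)
    expect_equal(back$origin, v$origin, tolerance = 1e-6)
    unlink(path)
  }
  fld <- deformation_field(array(rnorm(5 * 4 * 3 * 3), c(5, 4, 3, 3)),
                           c(1, 1, 1))
  path <- tempfile(fileext = ".nii.gz")
  write_nifti(fld, path)
  back <- read_nifti(path)
  expect_s3_class(back, "deformation_field")
  expect_equal(back$displacement, fld$displacement)
  unlink(path)
})
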