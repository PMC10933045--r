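test_that("RBE scaling multiplies proton dose by exactly 1.1, once", {
  d <- c(6, 6, 6)
  dose <- volume_grid(array(2, d), c(1, 1, 1))
  expect_equal(rbe_scale(dose, "proton")$values, array(2.2, d))
  expect_equal(rbe_scale(dose, "photon")$values, array(2, d))
  zero <- volume_grid(array(0, d), c(1, 1, 1))
  expect_equal(rbe_scale(zero, "proton")$values, array(0, d))
  expect_error(rbe_scale(dose, "carbon"), "unknown modality")
  scaled <- rbe_scale(dose, "proton")
  expect_error(rbe_scale(scaled, "proton"), "exactly once")
})

test_that("mean_dose and v_at_dose match their analytic cases", {
  d <- c(4, 1, 1)
  dose <- volume_grid(array(c(10, 20, 30, 40), d), c(1, 1, 1))
  mask <- volume_grid(array(1, d), c(1, 1, 1))
  expect_equal(mean_dose(dose, mask), 25.0)
  expect_equal(v_at_dose(dose, mask, 25), 50.0)
  expect_equal(v_at_dose(dose, mask, 0), 100.0)
  expect_equal(v_at_dose(dose, mask, 20), 75.0)  # >= is inclusive
  u <- volume_grid(array(7.5, d), c(1, 1, 1))
  expect_equal(mean_dose(u, mask), 7.5)
  expect_error(v_at_dose(dose, mask, -1), ">= 0")
  empty <- mask; empty$values[] <- 0
  expect_error(mean_dose(dose, empty), "empty")
})

test_that("cumulative DVH is monotone and consistent with v_at_dose", {
  d <- c(10, 10, 2)
  mask <- volume_grid(array(1, d), c(1, 1, 1))
  u <- volume_grid(array(50, d), c(1, 1, 1))
  cv <- cumulative_dvh(u, mask, bin_width = 1)
  expect_equal(cv$volume_percent[cv$dose_edges <= 50], rep(100, 51))
  expect_equal(cv$volume_percent[cv$dose_edges > 50], 0)

  two <- volume_grid(array(c(rep(30, 100), rep(60, 100)), d), c(1, 1, 1))
  cv <- cumulative_dvh(two, mask, bin_width = 0.5)
  expect_equal(cv$volume_percent[cv$dose_edges <= 30], rep(100, 61))
  mid <- cv$dose_edges > 30 & cv$dose_edges <= 60
  expect_equal(cv$volume_percent[mid], rep(50, sum(mid)))
  expect_equal(cv$volume_percent[cv$dose_edges > 60], 0)
  expect_true(all(diff(cv$volume_percent) <= 0))

  set.seed(14)
  dose <- random_dose(d)
  cv <- cumulative_dvh(dose, mask, bin_width = 0.1)
  for (x in runif(20, 0, 70)) {
    i <- which.min(abs(cv$dose_edges - x))
    expect_equal(cv$volume_percent[i], v_at_dose(dose, mask, cv$dose_edges[i]))
  }
  # mean dose equals the DVH integral / 100 (Riemann, bin-width tolerance)
  expect_equal(sum(cv$volume_percent) * 0.1 / 100, mean_dose(dose, mask),
               tolerance = 0.1)
  expect_error(cumulative_dvh(dose, mask, bin_width = 0), "bin_width")
})

test_that("v_at_dose is non-increasing in the threshold", {
  set.seed(15)
  dose <- random_dose(c(8, 8, 8))
  mask <- random_mask(c(8, 8, 8), p = 0.5)
  v <- vapply(seq(0, 75, by = 2.5), function(x) v_at_dose(dose, mask, x),
              numeric(1))
  expect_true(all(diff(v) <= 0))
})

test_that("the DVH feature set reproduces its analytic cases", {
  d <- c(10, 10, 10)
  pc <- box_mask(d, c(1, 1, 1), c(5, 5, 5))
  lar <- box_mask(d, c(6, 6, 6), c(10, 10, 10))
  u55 <- volume_grid(array(55, d), c(1, 1, 1))
  m <- dvh_feature_set(u55, pc, lar, "photon")
  expect_equal(unname(m[c("pc_v50", "pc_v55", "pc_v60")]), c(100, 100, 0))
  expect_equal(unname(m[c("larynx_v50", "larynx_v60")]), c(100, 0))
  expect_equal(unname(m[c("pc_mean_dose", "larynx_mean_dose")]), c(55, 55))
  expect_length(m, 7)
  expect_length(dvh_feature_set(u55, pc, lar, "photon", include_v65 = TRUE), 8)

  z <- volume_grid(array(0, d), c(1, 1, 1))
  mz <- dvh_feature_set(z, pc, lar, "proton")
  expect_equal(unname(mz[c("pc_mean_dose", "pc_v50", "larynx_v60")]), c(0, 0, 0))
  expect_error(dvh_feature_set(u55, NULL, lar), "both organ masks")
})
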