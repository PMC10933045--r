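test_that("make_reference is deterministic, symmetric, and size-checked", {
  r1 <- make_reference(smoke_shape, smoke_spacing, seed = 7)
  r2 <- make_reference(smoke_shape, smoke_spacing, seed = 7)
  expect_identical(r1$pc_mask$values, r2$pc_mask$values)
  expect_identical(r1$larynx_mask$values, r2$larynx_mask$values)
  expect_gte(dice(vg_flip_lr(r1$pc_mask), r1$pc_mask), 0.95)
  expect_gte(dice(vg_flip_lr(r1$larynx_mask), r1$larynx_mask), 0.95)
  # a different seed perturbs the outline but not the topology
  r3 <- make_reference(smoke_shape, smoke_spacing, seed = 8)
  expect_false(identical(r1$pc_mask$values, r3$pc_mask$values))
  expect_error(make_reference(c(10, 10, 10), c(1.27, 1.27, 1), seed = 1),
               "too small")
})

test_that("sample_patient is deterministic with an identity limit", {
  ref <- smoke_ref()
  c1 <- sample_patient(ref, seed = 31)
  c2 <- sample_patient(ref, seed = 31)
  expect_identical(c1$pc_mask$values, c2$pc_mask$values)
  expect_identical(c1$dose$values, c2$dose$values)
  expect_identical(c1$covariates, c2$covariates)

  id <- sample_patient(ref, seed = 5, max_displacement = 0,
                       affine_jitter = FALSE)
  expect_identical(id$pc_mask$values, ref$pc_mask$values)
  expect_identical(id$larynx_mask$values, ref$larynx_mask$values)
})

test_that("sampled prescriptions stay in 30-81.6 Gy and dose respects them", {
  ref <- smoke_ref()
  pres <- vapply(1:500, function(i) {
    sample_patient(ref, seed = 10000 + i, volumes = FALSE)$prescription
  }, numeric(1))
  expect_true(all(pres >= 30 & pres <= 81.6))

  for (s in 1:5) {
    cs <- sample_patient(ref, seed = 600 + s)
    expect_true(all(cs$dose$values >= 0))
    expect_lte(max(cs$dose$values), 1.1 * cs$prescription)
  }
})

test_that("assign_outcome follows the logistic truth model", {
  co <- smoke_cohort(n = 1000, seed = 2, volumes = FALSE,
                     truth = outcome_truth_model(intercept = 0,
                                                 dose_effect = 0,
                                                 covariate_effects = c(bilateral = 0)))
  y <- vapply(co$cases, function(c) c$outcome, numeric(1))
  # null model: prevalence = logistic(0) = 0.5 within 3 binomial SEs
  expect_lt(abs(mean(y) - 0.5), 3 * sqrt(0.25 / 1000))

  co2 <- generate_cohort(50, cohort_config(
    shape = smoke_shape, volumes = FALSE,
    truth = outcome_truth_model(intercept = -20, dose_effect = 0,
                                covariate_effects = c(bilateral = 0))), seed = 3)
  expect_true(all(vapply(co2$cases, function(c) c$outcome, numeric(1)) == 0))

  # with the default strong dose effect, outcome rate rises across quartiles
  co3 <- smoke_cohort(n = 200, seed = 4, volumes = FALSE)
  d <- vapply(co3$cases, function(c) c$planted_mean_dose, numeric(1))
  y <- vapply(co3$cases, function(c) c$outcome, numeric(1))
  qs <- cut(d, quantile(d, 0:4 / 4), include.lowest = TRUE)
  rates <- tapply(y, qs, mean)
  expect_true(all(diff(rates) >= 0))
})

test_that("outcome, feeding-tube events and weight records are consistent", {
  co <- smoke_cohort(n = 40, seed = 1, volumes = FALSE)
  for (cs in co$cases) {
    e <- extract_endpoint(cs$ft_days, cs$weight_records,
                          cs$rt_start_day, cs$rt_end_day)
    expect_true(e$eligible)
    expect_identical(e$outcome, as.integer(cs$outcome))
  }
})

test_that("generate_cohort enforces n >= 10 and is reproducible", {
  expect_error(generate_cohort(5, cohort_config(shape = smoke_shape)), "at least 10")
  a <- generate_cohort(12, cohort_config(shape = smoke_shape), seed = 9)
  b <- generate_cohort(12, cohort_config(shape = smoke_shape), seed = 9)
  expect_identical(clinical_table(a), clinical_table(b))
  expect_identical(a$cases[[3]]$dose$values, b$cases[[3]]$dose$values)
  expect_identical(a$cases[[7]]$pc_mask$values, b$cases[[7]]$pc_mask$values)
})

test_that("a study-sized cohort lands in the configured prevalence band", {
  cfg <- cohort_config(shape = smoke_shape, volumes = FALSE)
  co <- generate_cohort(231, cfg, seed = 5)
  expect_equal(length(co$cases), 231L)
  expect_gte(co$prevalence, cfg$prevalence_band[1])
  expect_lte(co$prevalence, cfg$prevalence_band[2])
})

test_that("univariate odds ratios recover the planted covariate signs", {
  co <- smoke_cohort(n = 2000, seed = 6, volumes = FALSE)
  clin <- clinical_table(co)
  eff <- co$truth$covariate_effects
  strong <- names(eff)[abs(eff) >= 0.5]
  for (nm in strong) {
    res <- univariate_logistic(clin[[nm]], clin$outcome, name = nm)
    expect_identical(sign(log(res$or)), sign(eff[[nm]]),
                     label = sprintf("OR sign for %s", nm))
  }
})

test_that("write_cohort produces NIfTI/CSV/JSON artifacts deterministically", {
  co <- smoke_cohort(n = 10, seed = 8, volumes = TRUE)
  d1 <- tempfile("cohort1_"); d2 <- tempfile("cohort2_")
  write_cohort(co, d1)
  co2 <- generate_cohort(10, cohort_config(shape = smoke_shape), seed = 8)
  write_cohort(co2, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_setequal(f1, f2)
  expect_true(all(c("clinical.csv", "truth.json", "reference_pc.nii.gz") %in% f1))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("checksum of", f))
  back <- read_nifti(file.path(d1, "case_0003_dose.nii.gz"))
  expect_equal(back$values, co$cases[[3]]$dose$values)
  unlink(c(d1, d2), recursive = TRUE)
})
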