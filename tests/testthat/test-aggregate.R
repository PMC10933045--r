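test_that("endpoint extraction implements the FT/WL rule exactly", {
  wr <- function(days, kg) data.frame(day = days, kg = kg)
  # 12.5% loss at day 40 -> positive
  e <- extract_endpoint(numeric(0), wr(c(-2, 40), c(80, 70)), 0, 0)
  expect_identical(e$outcome, 1L); expect_true(e$wl)
  # exactly 10% is not > 10% -> negative
  e <- extract_endpoint(numeric(0), wr(c(-2, 40), c(80, 72)), 0, 0)
  expect_identical(e$outcome, 0L)
  # feeding tube inside the 90-day window
  e <- extract_endpoint(30, wr(c(-2, 40), c(80, 79)), 0, 0)
  expect_identical(e$outcome, 1L); expect_true(e$ft)
  # tube before RT end or after day 90 does not count
  expect_identical(extract_endpoint(-5, wr(c(-2, 40), c(80, 79)), 0, 0)$outcome, 0L)
  expect_identical(extract_endpoint(95, wr(c(-2, 40), c(80, 79)), 0, 0)$outcome, 0L)
  # no baseline weight within +/- 2 weeks of RT start -> ineligible
  e <- extract_endpoint(numeric(0), wr(c(-30, 40), c(80, 60)), 0, 0)
  expect_false(e$eligible); expect_true(is.na(e$outcome))
})

test_that("component counts combine as a union (64 FT, 106 WL, 48 both -> 122)", {
  # constructed cohort with exactly the stated component counts
  n <- 231
  ft <- rep(FALSE, n); wl <- rep(FALSE, n)
  ft[1:64] <- TRUE
  wl[17:122] <- TRUE              # 48 overlap with FT (17..64), 106 total
  outcomes <- vapply(seq_len(n), function(i) {
    kg <- if (wl[i]) c(80, 68) else c(80, 78)
    extract_endpoint(if (ft[i]) 40 else numeric(0),
                     data.frame(day = c(-3, 50), kg = kg), 0, 0)$outcome
  }, integer(1))
  expect_equal(sum(ft), 64); expect_equal(sum(wl), 106)
  expect_equal(sum(ft & wl), 48)
  expect_equal(sum(outcomes), 122)
})

test_that("univariate logistic equals the 2x2 cross-product ratio", {
  y <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  x <- c(rep(1, 100), rep(0, 100))
  res <- univariate_logistic(x, y, "exposure")
  expect_equal(res$or, (30 * 90) / (70 * 10), tolerance = 1e-6)
  expect_true(res$ci_low < res$or && res$or < res$ci_high)
  expect_lt(res$p_value, 0.05)

  # null covariate: OR near 1
  set.seed(5)
  xn <- rnorm(1000); yn <- rbinom(1000, 1, 0.5)
  resn <- univariate_logistic(xn, yn)
  expect_lt(abs(log(resn$or)), 0.25)

  # complete separation is flagged with an unbounded interval
  ys <- rep(c(0, 1), each = 15)
  xs <- ys
  ress <- univariate_logistic(xs, ys)
  expect_true(ress$separated)
  expect_equal(ress$ci_high, Inf)
  expect_error(univariate_logistic(1:10, rep(0:1, 5)), "n >= 20")
})

test_that("covariate selection is strict-threshold and p-ordered", {
  res <- data.frame(
    variable = c("treatment_setting", "bilateral", "chemotherapy",
                 "baseline_weight", "adi", "dysphagia_grade0", "gender",
                 "modality", "smoker", "age"),
    p_value = c(1e-5, 1e-5, 0.001, 0.01, 0.02, 0.03, 0.16, 0.17, 0.34, 0.39))
  sel <- select_covariates(res)
  expect_length(sel, 6)
  expect_setequal(sel, res$variable[1:6])
  res$p_value[6] <- 0.05                     # exactly alpha -> excluded
  expect_length(select_covariates(res), 5)
  res$p_value[] <- 0.5
  expect_warning(sel0 <- select_covariates(res), "no covariate")
  expect_length(sel0, 0)
})

test_that("subregion partition follows the thirds rule and is exact", {
  ref <- smoke_ref()
  p <- partition_subregions(ref)
  lab <- p$labels
  idx_pc <- which(ref$pc_mask$values == 1)
  idx_l <- which(ref$larynx_mask$values == 1)
  expect_true(all(lab[idx_pc] %in% 1:6))
  expect_true(all(lab[idx_l] %in% 7:8))
  expect_equal(sum(lab > 0), length(idx_pc) + length(idx_l))

  # thirds by spanned z-slices: superior = top ceiling(span/3) slices
  a <- arrayInd(idx_pc, dim(lab))
  z <- a[, 3]
  span <- max(z) - min(z) + 1
  sup <- idx_pc[z > max(z) - ceiling(span / 3)]
  expect_setequal(which(lab %in% 1:2), sup)

  # uniform dose: all regional means equal the uniform value
  u <- volume_grid(array(63.2, dim(lab)), ref$spacing)
  rm <- region_mean_doses(u, p)
  expect_equal(unname(rm), rep(63.2, 8))
})

test_that("feature tables have the documented shapes (6 / 13 / 14)", {
  co <- smoke_cohort(n = 40, seed = 1, volumes = FALSE)
  clin <- clinical_table(co)
  fm <- truth_feature_matrix(co, "pc")
  fml <- truth_feature_matrix(co, "larynx")
  dvh <- features_dvh_table(fm, fml)
  reg <- features_regional_table(fm, fml, co$partition)
  sel <- c("treatment_setting", "bilateral", "chemotherapy",
           "baseline_weight", "adi", "dysphagia_grade0")
  tabs <- build_feature_tables(clin, dvh, reg, sel)
  expect_equal(ncol(tabs$clinical), 6)
  expect_equal(ncol(tabs$dvh), 13)
  expect_equal(ncol(tabs$regional), 14)
  expect_setequal(setdiff(colnames(tabs$regional), sel), co$partition$levels)
  expect_error(build_feature_tables(clin, dvh, reg, c(sel, "nope")), "missing")
  dvh_na <- dvh; dvh_na[3, 2] <- NA
  expect_error(build_feature_tables(clin, dvh_na, reg, sel), "missing DVH")
})

test_that("repeated trials are deterministic and track a planted signal", {
  co <- smoke_cohort(n = 120, seed = 33, volumes = FALSE)
  clin <- clinical_table(co)
  y <- setNames(clin$outcome, clin$id)
  fm <- truth_feature_matrix(co, "pc")
  fml <- truth_feature_matrix(co, "larynx")
  reg <- features_regional_table(fm, fml, co$partition)
  tr1 <- repeated_trials(reg, y, n_trials = 8, seed = 6)
  tr2 <- repeated_trials(reg, y, n_trials = 8, seed = 6)
  expect_identical(tr1$test_auc, tr2$test_auc)
  expect_length(tr1$test_auc, 8)
  expect_true(all(tr1$test_auc >= 0 & tr1$test_auc <= 1))
  expect_gte(tr1$auc_mean, 0.7)   # strong planted dose effect

  # permuted outcomes: near-chance mean AUC
  y0 <- setNames(with_seed(11, sample(y)), names(y))
  tr0 <- repeated_trials(reg, y0, n_trials = 8, seed = 7)
  expect_gte(tr0$auc_mean, 0.35)
  expect_lte(tr0$auc_mean, 0.65)
})

test_that("permutation importance isolates signal from noise features", {
  set.seed(21)
  n <- 150
  sig <- rnorm(n)
  y <- rbinom(n, 1, plogis(2.5 * sig))
  x <- cbind(signal = sig, noise1 = rnorm(n), noise2 = rnorm(n),
             noise3 = rnorm(n), constant = rep(1, n))
  pi <- permutation_importance(x, y, n_reps = 25, seed = 9)
  df <- as.data.frame(pi)
  expect_identical(df$feature[1], "signal")
  expect_lt(df$mean_auc_loss[df$feature == "signal"], -0.05)
  expect_lt(df$p_value[df$feature == "signal"], 0.01)
  noise <- df[grepl("noise", df$feature), ]
  expect_true(all(abs(noise$mean_auc_loss) <= 0.02))
  const_row <- df[df$feature == "constant", ]
  expect_true(const_row$constant)
  expect_equal(const_row$mean_auc_loss, 0)
})

test_that("model comparison uses the two-tailed rank-sum convention", {
  a <- seq(0.7, 0.9, length.out = 50)
  expect_equal(compare_models(a, a)$p_value, 1.0)
  b <- a + 0.5
  expect_lt(compare_models(b, a)$p_value, 1e-10)
  shuffled <- with_seed(3, sample(a))
  expect_gt(compare_models(a, shuffled)$p_value, 0.9)
  expect_equal(compare_models(rep(0.5, 50), rep(0.5, 50))$p_value, 1)
  expect_error(compare_models(a[1:5], a[1:5]), "length")
})
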