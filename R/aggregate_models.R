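#' Univariate logistic screen of one covariate
#'
#' Logistic regression of the binary FT/WL outcome on a single covariate;
#' reports the odds ratio (per unit for continuous covariates, per category
#' for binary ones), Wald 95% confidence interval and Wald p-value. Complete
#' separation is flagged and the interval reported as unbounded.
#'
#' @param x covariate vector.
#' @param y binary outcome vector (both classes present, n >= 20).
#' @param name variable name for the report.
#' @return one-row data.frame: `variable`, `or`, `ci_low`, `ci_high`,
#'   `p_value`, `separated`.
#' @export
univariate_logistic <- function(x, y, name = deparse(substitute(x))) {
  stopifnot(length(x) == length(y))
  if (length(y) < 20) stop("univariate screen requires n >= 20")
  if (length(unique(y)) < 2) stop("both outcome classes required")
  fit <- suppressWarnings(glm(y ~ x, family = binomial(),
                              control = list(maxit = 100, epsilon = 1e-12)))
  b <- coef(fit)[["x"]]
  se <- sqrt(vcov(fit)["x", "x"])
  separated <- !is.finite(se) || se > 50 || abs(b) > 20
  if (separated) {
    return(data.frame(variable = name, or = exp(b), ci_low = 0, ci_high = Inf,
                      p_value = NA_real_, separated = TRUE))
  }
  z <- b / se
  data.frame(variable = name, or = exp(b),
             ci_low = exp(b - 1.959964 * se), ci_high = exp(b + 1.959964 * se),
             p_value = 2 * pnorm(-abs(z)), separated = FALSE)
}

#' Run the univariate screen over a clinical table
#'
#' @param clinical data.frame of covariates (numeric/binary columns).
#' @param y binary outcome vector.
#' @param variables columns to screen (default: all).
#' @return data.frame of [univariate_logistic()] rows, ordered by ascending
#'   p-value.
#' @export
univariate_screen <- function(clinical, y, variables = names(clinical)) {
  res <- do.call(rbind, lapply(variables, function(v) {
    univariate_logistic(clinical[[v]], y, name = v)
  }))
  res[order(res$p_value), , drop = FALSE]
}

#' Select covariates significant in the univariate screen
#'
#' Strict `p < alpha`; ties at the boundary are excluded. Order follows
#' ascending p-value.
#'
#' @param results a [univariate_screen()] table.
#' @param alpha significance level (default 0.05).
#' @return character vector of selected variable names (possibly empty, with
#'   a warning).
#' @export
select_covariates <- function(results, alpha = 0.05) {
  keep <- !is.na(results$p_value) & results$p_value < alpha
  sel <- results$variable[keep][order(results$p_value[keep])]
  if (length(sel) == 0) warning("no covariate passed the univariate screen")
  sel
}

#' Assemble the three aggregate model feature tables
#'
#' (a) clinical-only: the selected covariates; (b) DVH model: covariates +
#' the 7 DVH metrics; (c) regional model: covariates + the 8 subregion mean
#' doses. Categorical covariates are expected one-hot encoded (0/1 columns)
#' in `clinical`; standardization is deferred to fold level inside the
#' trainers.
#'
#' @param clinical data.frame (rows = patients) containing the selected
#'   covariate columns.
#' @param dvh_metrics matrix/data.frame of the 7 DVH metrics per patient.
#' @param regional_doses matrix/data.frame of the 8 regional mean doses.
#' @param selected character vector of covariate names.
#' @return list of numeric matrices: `clinical`, `dvh`, `regional`.
#' @export
build_feature_tables <- function(clinical, dvh_metrics, regional_doses,
                                 selected) {
  miss <- setdiff(selected, names(clinical))
  if (length(miss)) stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  base <- as.matrix(clinical[, selected, drop = FALSE])
  check_block <- function(m, what) {
    m <- as.matrix(m)
    if (anyNA(m)) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("missing %s metric '%s' for patient row %d", what,
                   colnames(m)[bad[2]], bad[1]))
    }
    m
  }
  list(clinical = base,
       dvh = cbind(base, check_block(dvh_metrics, "DVH")),
       regional = cbind(base, check_block(regional_doses, "regional-dose")))
}

#' Repeated train/test trials of an aggregate ridge model
#'
#' Each trial draws a fresh stratified 80/20 split, tunes the ridge penalty
#' by stratified 5-fold cross-validated AUC with fold-level standardization,
#' refits on the full training set and records the test AUC and F1.
#'
#' @param x feature matrix.
#' @param y binary outcomes.
#' @param n_trials number of trials (default 50).
#' @param folds CV folds (default 5).
#' @param test_fraction held-out fraction per trial.
#' @param lambdas penalty grid.
#' @param seed master seed; trial seeds derive from it.
#' @param keep_predictions also store per-trial test-set scores and labels
#'   (for ROC plotting).
#' @return list of class `trial_distribution`: `test_auc`, `f1` (per-trial
#'   vectors), `auc_mean`, `auc_sd`, `f1_mean`, `f1_sd`, `lambda` (per
#'   trial), and `predictions` (data.frame trial/score/label) when requested.
#' @export
repeated_trials <- function(x, y, n_trials = 50, folds = 5,
                            test_fraction = 0.2, lambdas = penalty_grid(),
                            seed = 1, keep_predictions = FALSE) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2) stop("both classes required")
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  rownames(x) <- ids
  names(y) <- ids
  aucs <- f1s <- lam <- numeric(0)
  preds <- list()
  failures <- 0
  t <- 1
  while (length(aucs) < n_trials) {
    s <- derive_seed(seed, sprintf("trial_%04d", t))
    t <- t + 1
    res <- tryCatch({
      sp <- split_cohort(ids, y, test_fraction, s)
      tune <- tune_ridge(x[sp$train, , drop = FALSE], y[sp$train],
                         folds = folds, lambdas = lambdas,
                         seed = derive_seed(s, "cv"))
      model <- fit_ridge(x[sp$train, , drop = FALSE], y[sp$train],
                         tune$lambda, lambdas)
      ev <- evaluate_model(model, x[sp$test, , drop = FALSE], y[sp$test])
      list(stats = c(ev$test_auc, ev$f1, tune$lambda),
           pred = if (keep_predictions) {
             data.frame(trial = length(aucs) + 1,
                        score = predict(model, x[sp$test, , drop = FALSE]),
                        label = as.integer(y[sp$test]))
           })
    }, error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1
      vd_log("trial failed (%d so far), retrying with a new seed", failures,
             verbose = TRUE)
      if (failures > max(2, 0.1 * n_trials))
        stop("more than 10% of trials failed")
      next
    }
    aucs <- c(aucs, res$stats[1]); f1s <- c(f1s, res$stats[2])
    lam <- c(lam, res$stats[3])
    if (keep_predictions) preds[[length(preds) + 1]] <- res$pred
  }
  structure(list(test_auc = aucs, f1 = f1s, lambda = lam,
                 predictions = if (keep_predictions) do.call(rbind, preds),
                 auc_mean = mean(aucs), auc_sd = sd(aucs),
                 f1_mean = mean(f1s), f1_sd = sd(f1s),
                 n_trials = n_trials, failures = failures),
            class = "trial_distribution")
}

#' Permutation feature importance with cross-validation
#'
#' For each repetition, draws a stratified 5-fold partition, fits the ridge
#' model (at a penalty tuned once on the intact data) on each fold's
#' training part, and evaluates validation AUC with the intact data and with
#' one feature's validation values permuted at a time (shuffling lands in
#' the validation part after fitting on intact training data). The mean
#' AUC change (permuted minus intact; negative = performance drop) over
#' repetitions measures importance; a two-tailed Wilcoxon rank-sum test
#' compares the permuted and intact AUC samples. By default every
#' repetition resamples its folds; `resample_folds = FALSE` reuses one
#' partition.
#'
#' @param x feature matrix (the training dataset).
#' @param y binary outcomes.
#' @param n_reps permutation repetitions per feature (default 50).
#' @param folds CV folds (default 5).
#' @param lambdas penalty grid for the one-off tuning.
#' @param resample_folds redraw folds per repetition (default TRUE).
#' @param seed master seed.
#' @return data.frame of class `permutation_importance`, one row per
#'   feature: `feature`, `mean_auc_loss` (signed), `p_value`, `constant`;
#'   ordered by loss magnitude. The per-repetition intact AUCs are attached
#'   as attribute `"auc_intact"`.
#' @export
permutation_importance <- function(x, y, n_reps = 50, folds = 5,
                                   lambdas = penalty_grid(),
                                   resample_folds = TRUE, seed = 1) {
  x <- as.matrix(x)
  p <- ncol(x)
  feats <- colnames(x) %||% paste0("V", seq_len(p))
  tune <- tune_ridge(x, y, folds = folds, lambdas = lambdas,
                     seed = derive_seed(seed, "tune"))
  const <- apply(x, 2, function(col) var(col) < 1e-24)
  auc_intact <- numeric(n_reps)
  auc_perm <- matrix(NA_real_, n_reps, p)
  fold0 <- stratified_folds(y, folds, derive_seed(seed, "folds"))
  for (r in seq_len(n_reps)) {
    fo <- if (resample_folds) {
      stratified_folds(y, folds, derive_seed(seed, sprintf("folds_%04d", r)))
    } else fold0
    ai <- ap <- matrix(NA_real_, folds, p)
    aint <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- which(fo != f); va <- which(fo == f)
      if (length(unique(y[va])) < 2 || length(unique(y[tr])) < 2) {
        aint[f] <- NA; next
      }
      model <- fit_ridge(x[tr, , drop = FALSE], y[tr], tune$lambda, lambdas)
      aint[f] <- auc_roc(predict(model, x[va, , drop = FALSE]), y[va])
      perm <- with_seed(derive_seed(seed, sprintf("perm_%04d_%d", r, f)),
                        sample(length(va)))
      for (j in seq_len(p)) {
        if (const[j]) { ap[f, j] <- aint[f]; next }
        xp <- x[va, , drop = FALSE]
        xp[, j] <- xp[perm, j]
        ap[f, j] <- auc_roc(predict(model, xp), y[va])
      }
    }
    auc_intact[r] <- mean(aint, na.rm = TRUE)
    auc_perm[r, ] <- colMeans(ap, na.rm = TRUE)
  }
  loss <- colMeans(auc_perm) - mean(auc_intact)
  pv <- vapply(seq_len(p), function(j) {
    if (const[j]) return(1)
    if (length(unique(c(auc_perm[, j], auc_intact))) == 1) return(1)
    suppressWarnings(wilcox.test(auc_perm[, j], auc_intact, exact = FALSE,
                                 correct = FALSE)$p.value)
  }, numeric(1))
  out <- data.frame(feature = feats, mean_auc_loss = loss, p_value = pv,
                    constant = const, row.names = NULL)
  out <- out[order(-abs(out$mean_auc_loss)), , drop = FALSE]
  attr(out, "auc_intact") <- auc_intact
  attr(out, "lambda") <- tune$lambda
  class(out) <- c("permutation_importance", "data.frame")
  out
}

#' Compare two trial AUC distributions (two-tailed Wilcoxon rank-sum)
#'
#' Uses the normal approximation without continuity correction, so identical
#' samples give p exactly 1. Degenerate input (every value identical across
#' both samples) returns p = 1 by definition.
#'
#' @param auc_a,auc_b equal-length AUC samples (n >= 10).
#' @return list: `p_value`, `statistic`, `mean_a`, `sd_a`, `mean_b`, `sd_b`.
#' @export
compare_models <- function(auc_a, auc_b) {
  stopifnot(length(auc_a) == length(auc_b), length(auc_a) >= 10)
  base <- list(mean_a = mean(auc_a), sd_a = sd(auc_a),
               mean_b = mean(auc_b), sd_b = sd(auc_b))
  if (length(unique(c(auc_a, auc_b))) == 1)
    return(c(list(p_value = 1, statistic = length(auc_a)^2 / 2), base))
  wt <- suppressWarnings(wilcox.test(auc_a, auc_b, exact = FALSE,
                                     correct = FALSE))
  c(list(p_value = wt$p.value, statistic = unname(wt$statistic)), base)
}
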