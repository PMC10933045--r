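# Ridge logistic regression machinery shared by the voxel and aggregate
# models: rank-based AUC, training-set standardization, stratified splits and
# folds, penalty tuning by 5-fold cross-validated AUC, final fit and report.
# The solver is glmnet (alpha = 0, standardize = FALSE); all split,
# standardization and evaluation logic is package code.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC; tied scores contribute 1/2, so a constant
#' score gives 0.5.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 outcomes (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC requires both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Training-set standardization
#'
#' Centers and scales every column to mean 0 / sd 1 using statistics of the
#' training rows only (population sd, n denominator); held-out rows are
#' transformed with the training parameters. Zero-variance training columns
#' are centered and left at 0 (retained, flagged), keeping column alignment
#' stable.
#'
#' @param x numeric matrix (all rows).
#' @param train_idx row indices of the training set (>= 2 rows).
#' @return list: `x` (transformed full matrix), `params` (list `mean`, `sd`,
#'   `zero_variance`).
#' @export
standardize <- function(x, train_idx) {
  x <- as.matrix(x)
  if (length(train_idx) < 2) stop("standardization needs >= 2 training rows")
  xt <- x[train_idx, , drop = FALSE]
  mu <- colMeans(xt)
  s <- sqrt(colMeans(sweep(xt, 2, mu)^2))
  zv <- s < 1e-12
  s[zv] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, s, "/")
  xs[, zv] <- 0
  list(x = xs, params = list(mean = mu, sd = s, zero_variance = zv))
}

apply_standardization <- function(x, params) {
  xs <- sweep(sweep(as.matrix(x), 2, params$mean), 2, params$sd, "/")
  xs[, params$zero_variance] <- 0
  xs
}

#' Stratified train/test split
#'
#' Splits patients 80/20 (by default) stratified by outcome. Flip-augmented
#' copies are not split here: they inherit their source patient's assignment
#' downstream, so a patient and its mirror never straddle the split. If a
#' draw leaves the training set single-class, the split is redrawn with an
#' incremented seed (logged).
#'
#' @param ids patient identifiers.
#' @param outcomes binary outcomes aligned with `ids`.
#' @param test_fraction held-out fraction (default 0.2).
#' @param seed integer seed.
#' @return list: `train`, `test` (character ids), `seed_used`.
#' @export
split_cohort <- function(ids, outcomes, test_fraction = 0.2, seed = 1) {
  stopifnot(length(ids) == length(outcomes), length(ids) >= 10)
  for (try in 0:20) {
    s <- seed + try
    test <- with_seed(s, {
      unlist(lapply(unique(outcomes), function(cl) {
        pool <- ids[outcomes == cl]
        n_test <- round(length(pool) * test_fraction)
        sample(pool, n_test)
      }), use.names = FALSE)
    })
    train <- setdiff(ids, test)
    if (length(unique(outcomes[ids %in% train])) == 2 && length(test) > 0) {
      if (try > 0) vd_log("split reshuffled %d time(s) to avoid a single-class training set", try)
      return(list(train = train, test = test, seed_used = s))
    }
  }
  stop("could not produce a two-class training split")
}

# fold assignment per patient, stratified by outcome
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    f <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
}

#' Default ridge penalty search grid
#'
#' Log-spaced over `[1e-4, 1e4]`, 50 values (descending, as the solver
#' expects).
#'
#' @param n number of grid points.
#' @param range penalty range.
#' @return numeric vector of penalties, descending.
#' @export
penalty_grid <- function(n = 50, range = c(1e-4, 1e4)) {
  sort(exp(seq(log(range[1]), log(range[2]), length.out = n)), decreasing = TRUE)
}

glmnet_fit <- function(x, y, lambdas) {
  if (ncol(x) < 2) x <- cbind(x, `.dummy` = 0)
  glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lambdas,
                 standardize = FALSE, thresh = 1e-8, maxit = 1e5)
}

# Ridge logistic path with an exact wide-data reduction: with an unpenalized
# intercept and pure L2 penalty, the solution lies in the row space of x, so
# for p >> n the fit on the thin-SVD scores Z = U D (with beta = V gamma)
# is exactly equivalent and orders of magnitude faster on voxel matrices.
ridge_path_fit <- function(x, y, lambdas) {
  n <- nrow(x); p <- ncol(x)
  if (p > n + 1) {
    sv <- svd(x)
    r <- max(1L, sum(sv$d > 1e-10 * sv$d[1]))
    z <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
    list(fit = glmnet_fit(z, y, lambdas),
         V = sv$v[, seq_len(r), drop = FALSE], p = p)
  } else {
    list(fit = glmnet_fit(x, y, lambdas), V = NULL, p = p)
  }
}

ridge_path_link <- function(obj, newx, s) {
  nx <- if (!is.null(obj$V)) newx %*% obj$V else newx
  if (ncol(nx) < 2) nx <- cbind(nx, `.dummy` = 0)
  predict(obj$fit, newx = nx, s = s, type = "link")
}

ridge_path_coef <- function(obj, s) {
  cf <- as.numeric(coef(obj$fit, s = s))
  beta <- cf[-1]
  if (!is.null(obj$V)) beta <- as.numeric(obj$V %*% beta[seq_len(ncol(obj$V))])
  list(intercept = cf[1], beta = beta[seq_len(obj$p)])
}

#' Tune the ridge penalty by stratified 5-fold cross-validated AUC
#'
#' Standardization parameters are recomputed inside every fold from that
#' fold's training part only. Flip-augmented rows (marked by `flipped`) join
#' their source patient's fold but are used in training parts only, never for
#' validation, to avoid twin leakage.
#'
#' @param x feature matrix (pre-standardization), rows = patients (+ any
#'   augmented copies).
#' @param y binary outcomes per row.
#' @param groups source-patient id per row (augmented rows share their
#'   source's id); defaults to one group per row.
#' @param flipped logical per row; `TRUE` marks augmented copies.
#' @param folds number of CV folds (default 5).
#' @param lambdas penalty grid (descending; see [penalty_grid()]).
#' @param seed integer seed for the fold assignment.
#' @param rule `"best"` selects the penalty maximizing mean validation AUC;
#'   `"1se"` selects the largest penalty whose mean validation AUC is within
#'   one standard error of the best (more regularized, spatially stabler
#'   coefficient maps — used by the voxel models).
#' @return list: `lambda` (selected), `cv_auc_mean`, `cv_auc_sd` (at the
#'   selected penalty), `trace` (per-penalty mean/sd of validation AUC).
#' @export
tune_ridge <- function(x, y, groups = NULL, flipped = NULL, folds = 5,
                       lambdas = penalty_grid(), seed = 1,
                       rule = c("best", "1se")) {
  rule <- match.arg(rule)
  x <- as.matrix(x)
  if (length(unique(y)) < 2) stop("penalty tuning requires both classes")
  if (is.null(groups)) groups <- seq_len(nrow(x))
  if (is.null(flipped)) flipped <- rep(FALSE, nrow(x))
  ug <- unique(groups[!flipped])
  gy <- y[!flipped][match(ug, groups[!flipped])]
  gf <- stratified_folds(gy, folds, seed)
  fold_of_row <- gf[match(groups, ug)]
  aucs <- matrix(NA_real_, folds, length(lambdas))
  for (f in seq_len(folds)) {
    tr <- which(fold_of_row != f)
    va <- which(fold_of_row == f & !flipped)
    if (length(unique(y[va])) < 2 || length(unique(y[tr])) < 2) next
    st <- standardize(x, tr)
    fit <- ridge_path_fit(st$x[tr, , drop = FALSE], y[tr], lambdas)
    pr <- ridge_path_link(fit, st$x[va, , drop = FALSE], lambdas)
    aucs[f, ] <- apply(pr, 2, auc_roc, labels = y[va])
  }
  mean_auc <- colMeans(aucs, na.rm = TRUE)
  sd_auc <- apply(aucs, 2, sd, na.rm = TRUE)
  best <- which.max(mean_auc)  # ties resolve to the largest penalty (first)
  if (rule == "1se") {
    se <- sd_auc[best] / sqrt(sum(is.finite(aucs[, best])))
    # grid is descending, so the first index meeting the bar is the largest
    best <- which(mean_auc >= mean_auc[best] - se)[1]
  }
  list(lambda = lambdas[best], cv_auc_mean = mean_auc[best],
       cv_auc_sd = sd_auc[best],
       trace = data.frame(lambda = lambdas, cv_auc_mean = mean_auc,
                          cv_auc_sd = sd_auc))
}

#' Final ridge fit at a chosen penalty
#'
#' Standardizes on all supplied rows (the full training set, including any
#' augmented copies), fits at the tuned penalty and reports the training AUC.
#'
#' @param x training feature matrix (pre-standardization).
#' @param y binary outcomes.
#' @param lambda penalty from [tune_ridge()].
#' @param lambdas grid used to stabilize the solver path.
#' @return an object of class `ridge_model`: standardized-scale coefficients
#'   `beta`, `intercept`, `lambda`, standardization `params`, `train_auc`.
#' @export
fit_ridge <- function(x, y, lambda, lambdas = penalty_grid()) {
  x <- as.matrix(x)
  st <- standardize(x, seq_len(nrow(x)))
  path <- sort(unique(c(lambdas[lambdas >= lambda], lambda)), decreasing = TRUE)
  fit <- ridge_path_fit(st$x, y, path)
  cf <- ridge_path_coef(fit, lambda)
  if (!all(is.finite(c(cf$intercept, cf$beta))))
    stop("ridge fit did not converge (non-finite coefficients); lambda = ", lambda)
  scores <- as.numeric(st$x %*% cf$beta) + cf$intercept
  structure(list(beta = stats::setNames(cf$beta, colnames(x)),
                 intercept = cf$intercept, lambda = lambda, params = st$params,
                 train_auc = auc_roc(scores, y)),
            class = "ridge_model")
}

#' Predict FT/WL probabilities from a ridge model
#'
#' @param object a `ridge_model`.
#' @param newdata feature matrix on the original (unstandardized) scale.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.ridge_model <- function(object, newdata, ...) {
  xs <- apply_standardization(as.matrix(newdata), object$params)
  plogis(as.numeric(xs %*% object$beta) + object$intercept)
}

#' Evaluate a fitted model on held-out data
#'
#' Accuracy and F1 use the positive class FT/WL = 1 at probability threshold
#' 0.5.
#'
#' @param model a `ridge_model`.
#' @param x_test,y_test held-out features and outcomes.
#' @param threshold classification threshold (default 0.5).
#' @return list: `test_auc`, `accuracy`, `f1`.
#' @export
evaluate_model <- function(model, x_test, y_test, threshold = 0.5) {
  p <- predict(model, x_test)
  yhat <- as.integer(p >= threshold)
  tp <- sum(yhat == 1 & y_test == 1)
  fp <- sum(yhat == 1 & y_test == 0)
  fn <- sum(yhat == 0 & y_test == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(test_auc = auc_roc(p, y_test),
       accuracy = mean(yhat == y_test),
       f1 = f1)
}
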