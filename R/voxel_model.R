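#' Build the cohort-by-voxel dose feature matrix
#'
#' One column per 1-voxel of the reference organ mask in column-major scan
#' order; one row per supplied (reference-frame) dose grid. The voxel index
#' stored with the matrix maps every column back to its reference-grid
#' coordinate exactly.
#'
#' @param warped_doses named list of dose `volume_grid`s on the reference
#'   grid (names become patient ids).
#' @param ref_mask reference organ mask (`volume_grid`).
#' @param organ `"pc"` or `"larynx"`.
#' @return an object of class `voxel_feature_matrix`: `values` (patients x
#'   voxels, Gy), `voxel_index` (column -> linear grid index), `patient_ids`,
#'   `organ`, grid metadata.
#' @export
extract_features <- function(warped_doses, ref_mask, organ = c("pc", "larynx")) {
  organ <- match.arg(organ)
  assert_mask(ref_mask)
  idx <- which(ref_mask$values == 1)
  rows <- lapply(warped_doses, function(dv) {
    stopifnot(is_volume_grid(dv))
    if (!same_grid(dv, ref_mask)) stop("dose grid does not match the reference grid")
    as.numeric(dv$values)[idx]
  })
  m <- do.call(rbind, rows)
  if (anyNA(m)) stop("voxel feature matrix contains missing values")
  ids <- names(warped_doses) %||% as.character(seq_along(warped_doses))
  rownames(m) <- ids
  structure(list(values = m, voxel_index = idx, patient_ids = ids,
                 organ = organ, dim = vg_dim(ref_mask),
                 spacing = ref_mask$spacing, origin = ref_mask$origin),
            class = "voxel_feature_matrix")
}

#' Reconstruct a 3D map from per-voxel values
#'
#' Inverse of the flattening done by [extract_features()]: values are placed
#' at their reference-grid coordinates, zero elsewhere.
#'
#' @param values numeric vector, one entry per column of the feature matrix.
#' @param fm a `voxel_feature_matrix` (provides the voxel index and grid).
#' @return a `volume_grid` (e.g. a coefficient map).
#' @export
voxels_to_map <- function(values, fm) {
  stopifnot(inherits(fm, "voxel_feature_matrix"),
            length(values) == length(fm$voxel_index))
  arr <- array(0, fm$dim)
  arr[fm$voxel_index] <- values
  volume_grid(arr, fm$spacing, fm$origin)
}

#' Fit and evaluate a voxel-dose ridge model
#'
#' Splits the cohort 80/20 stratified by outcome, optionally doubles the
#' training rows with left-right flipped dose copies (training and
#' within-fold training parts only), tunes the ridge penalty by stratified
#' 5-fold cross-validated AUC, refits on the full training data, and maps
#' the standardized-scale coefficients back into the reference frame as a 3D
#' feature-importance map.
#'
#' @param fm a [extract_features()] matrix for the original cohort.
#' @param outcomes named binary vector (names = patient ids).
#' @param fm_flipped optional matrix of the same shape holding each
#'   patient's mirrored warped dose (enables flip augmentation).
#' @param test_fraction,folds,lambdas,seed modeling controls.
#' @param rule penalty selection rule (see [tune_ridge()]); the default
#'   `"1se"` trades a sliver of cross-validated AUC for substantially more
#'   regularized, spatially coherent coefficient maps — the quantity this
#'   model exists to produce.
#' @return list of class `voxel_model`: `report` (lambda, cv/train/test AUC,
#'   accuracy, F1, train AUC with and without augmented rows), `model`
#'   (`ridge_model`), `coefficient_map` (`volume_grid`), `split`, `fm`.
#' @export
fit_voxel_model <- function(fm, outcomes, fm_flipped = NULL,
                            test_fraction = 0.2, folds = 5,
                            lambdas = penalty_grid(), seed = 1,
                            rule = "1se") {
  stopifnot(inherits(fm, "voxel_feature_matrix"))
  ids <- fm$patient_ids
  y <- outcomes[ids]
  stopifnot(!anyNA(y))
  sp <- split_cohort(ids, y, test_fraction, derive_seed(seed, "split"))
  tr_ids <- sp$train
  x_tr <- fm$values[tr_ids, , drop = FALSE]
  y_tr <- y[tr_ids]
  groups <- tr_ids
  flip <- rep(FALSE, length(tr_ids))
  if (!is.null(fm_flipped)) {
    stopifnot(identical(dim(fm_flipped$values), dim(fm$values)))
    x_tr <- rbind(x_tr, fm_flipped$values[tr_ids, , drop = FALSE])
    y_tr <- c(y_tr, y[tr_ids])
    groups <- c(groups, tr_ids)
    flip <- c(flip, rep(TRUE, length(tr_ids)))
  }
  tune <- tune_ridge(x_tr, y_tr, groups = groups, flipped = flip,
                     folds = folds, lambdas = lambdas,
                     seed = derive_seed(seed, "cv"), rule = rule)
  model <- fit_ridge(x_tr, y_tr, tune$lambda, lambdas)
  ev <- evaluate_model(model, fm$values[sp$test, , drop = FALSE], y[sp$test])
  # training AUC restricted to unaugmented rows, for reporting
  p_orig <- predict(model, fm$values[tr_ids, , drop = FALSE])
  report <- list(lambda = tune$lambda,
                 cv_auc_mean = tune$cv_auc_mean, cv_auc_sd = tune$cv_auc_sd,
                 train_auc = model$train_auc,
                 train_auc_unaugmented = auc_roc(p_orig, y[tr_ids]),
                 test_auc = ev$test_auc, accuracy = ev$accuracy, f1 = ev$f1,
                 n_train = length(tr_ids), n_test = length(sp$test),
                 n_rows_fit = nrow(x_tr),
                 augmented = !is.null(fm_flipped), organ = fm$organ)
  structure(list(report = report, model = model,
                 coefficient_map = voxels_to_map(model$beta, fm),
                 split = sp, tune = tune, fm = fm),
            class = "voxel_model")
}

#' Subregion shares of the top-coefficient voxels
#'
#' For the top `q`% of organ voxels ranked by absolute coefficient, the
#' fraction falling in each subregion of the partition (shares sum to 1).
#'
#' @param map coefficient map (`volume_grid` on the reference grid).
#' @param partition a [partition_subregions()] result.
#' @param q top percentage by `|coefficient|`, in `(0, 100]` (default 5).
#' @return named numeric vector of shares over the 8 subregions.
#' @export
importance_summary <- function(map, partition, q = 5) {
  if (q <= 0 || q > 100) stop("q must be in (0, 100]")
  stopifnot(is_volume_grid(map), inherits(partition, "subregion_partition"))
  organ_idx <- which(map$values != 0 | partition$labels > 0)
  organ_idx <- organ_idx[partition$labels[organ_idx] > 0]
  v <- abs(map$values[organ_idx])
  keep <- v > 0
  organ_idx <- organ_idx[keep]; v <- v[keep]
  n_top <- max(1L, ceiling(length(v) * q / 100))
  top <- organ_idx[order(v, decreasing = TRUE)[seq_len(n_top)]]
  lab <- partition$labels[top]
  shares <- tabulate(lab, nbins = length(partition$levels)) / length(top)
  stats::setNames(shares, partition$levels)
}
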