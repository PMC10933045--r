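#' Normalize a cohort's organ masks and doses into the reference frame
#'
#' For every case, estimates (or looks up) the deformation mapping the
#' reference frame onto the patient, computes Dice QC, and pulls the
#' RBE-scaled patient dose back onto the reference grid. The two organs are
#' registered independently. With `method = "register"` the in-package
#' contour registration is run; with `method = "truth"` the generator's own
#' deformation is used (exact normalization, available for synthetic cohorts
#' only — useful to test the downstream models independently of registration
#' accuracy). With `augment_flip = TRUE` each case's left-right mirrored
#' copy is normalized as well (its mask registered to the unflipped
#' reference in the same manner as the original data).
#'
#' @param cohort a [generate_cohort()] result with materialized volumes
#'   (`method = "truth"` works without volumes).
#' @param organ `"pc"` or `"larynx"`.
#' @param method `"register"` or `"truth"`.
#' @param params [registration_params()].
#' @param augment_flip also normalize mirrored copies.
#' @return list: `warped_doses` (named list of reference-frame dose
#'   `volume_grid`s, RBE-scaled), `flipped_doses` (when augmented), `qc`
#'   (data.frame id/organ/dice_before/dice_after/pass), `fields`.
#' @export
normalize_cohort <- function(cohort, organ = c("pc", "larynx"),
                             method = c("register", "truth"),
                             params = registration_params(),
                             augment_flip = FALSE) {
  organ <- match.arg(organ)
  method <- match.arg(method)
  ref <- cohort$reference
  ref_mask <- if (organ == "pc") ref$pc_mask else ref$larynx_mask
  d <- ref$shape
  warped <- flipped <- fields <- list()
  qc <- data.frame()
  for (cs in cohort$cases) {
    if (method == "truth") {
      fld <- truth_field_of(cs, ref)
      vals <- dose_eval(cs$dose_params,
                        vg_coords(ref_mask) + matrix(fld$displacement, ncol = 3))
      wd <- volume_grid(array(vals, d), ref$spacing, ref$origin)
      if (cs$modality == "proton") wd$values <- wd$values * 1.1
      attr(wd, "rbe_scaled") <- TRUE
      db <- da <- NA_real_
      if (!is.null(cs$pc_mask)) {
        pm <- if (organ == "pc") cs$pc_mask else cs$larynx_mask
        db <- dice(pm, ref_mask)
        da <- dice(warp(pm, fld, "nearest"), ref_mask)
      }
      qc <- rbind(qc, data.frame(id = cs$id, organ = organ, dice_before = db,
                                 dice_after = da, pass = TRUE))
      warped[[cs$id]] <- wd
      fields[[cs$id]] <- fld
      if (augment_flip) flipped[[cs$id]] <- vg_flip_lr(wd)
    } else {
      pm <- if (organ == "pc") cs$pc_mask else cs$larynx_mask
      stopifnot(is_volume_grid(pm))
      reg <- register(pm, ref_mask, params)
      pd <- rbe_scale(cs$dose, cs$modality)
      warped[[cs$id]] <- warp(pd, reg$field, "linear")
      attr(warped[[cs$id]], "rbe_scaled") <- TRUE
      fields[[cs$id]] <- reg$field
      qc <- rbind(qc, data.frame(id = cs$id, organ = organ,
                                 dice_before = reg$qc$dice_before,
                                 dice_after = reg$qc$dice_after,
                                 pass = reg$qc$pass_flag))
      if (augment_flip) {
        fm <- vg_flip_lr(pm)
        regf <- register(fm, ref_mask, params)
        fdw <- warp(vg_flip_lr(pd), regf$field, "linear")
        attr(fdw, "rbe_scaled") <- TRUE
        flipped[[cs$id]] <- fdw
        qc <- rbind(qc, data.frame(id = paste0(cs$id, "_flip"), organ = organ,
                                   dice_before = regf$qc$dice_before,
                                   dice_after = regf$qc$dice_after,
                                   pass = regf$qc$pass_flag))
      }
    }
  }
  n_fail <- sum(!qc$pass)
  if (n_fail > 0)
    vd_log("%d registration(s) failed the Dice QC gate and are flagged for exclusion",
           n_fail, verbose = TRUE)
  list(warped_doses = warped,
       flipped_doses = if (augment_flip) flipped else NULL,
       qc = qc, fields = fields, organ = organ, method = method)
}

#' Regional mean-dose table for a cohort
#'
#' PC subregion doses come from the PC-registered warped dose, larynx
#' subregion doses from the larynx-registered warped dose.
#'
#' @param norm_pc,norm_larynx [normalize_cohort()] results for the two
#'   organs.
#' @param partition a [partition_subregions()] result.
#' @return matrix, rows = patients, 8 columns of regional mean doses (Gy).
#' @export
regional_dose_table <- function(norm_pc, norm_larynx, partition) {
  ids <- names(norm_pc$warped_doses)
  out <- t(vapply(ids, function(id) {
    rp <- region_mean_doses(norm_pc$warped_doses[[id]], partition)
    rl <- region_mean_doses(norm_larynx$warped_doses[[id]], partition)
    c(rp[1:6], rl[7:8])
  }, numeric(8)))
  rownames(out) <- ids
  out
}

#' DVH metric table for a cohort (patient frame)
#'
#' @param cohort a [generate_cohort()] result with materialized volumes.
#' @param include_v65 see [dvh_feature_set()].
#' @return matrix, rows = patients, 7 (or 8) DVH metric columns.
#' @export
dvh_metric_table <- function(cohort, include_v65 = FALSE) {
  rows <- lapply(cohort$cases, function(cs) {
    dvh_feature_set(cs$dose, cs$pc_mask, cs$larynx_mask, cs$modality,
                    include_v65 = include_v65)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(cohort$cases, function(cs) cs$id, character(1))
  out
}

# ---- lean truth-frame feature paths ---------------------------------------
# For synthetic cohorts the generating deformation and the analytic dose
# model allow reference-frame features to be computed directly at the organ
# voxels, without materializing any full-grid volume. These paths back the
# large recovery simulations, where holding hundreds of warped grids in
# memory would be wasteful.

truth_case_row <- function(cs, ref, idx, coords) {
  v <- dose_eval(cs$dose_params, coords + truth_warp_eval(cs$truth_warp, coords))
  if (cs$modality == "proton") v * 1.1 else v
}

#' Reference-frame voxel dose matrix through the generating deformation
#'
#' @param cohort a [generate_cohort()] result.
#' @param organ `"pc"` or `"larynx"`.
#' @param flip evaluate at left-right mirrored reference voxels instead
#'   (the flip-augmented copy of every patient).
#' @return a `voxel_feature_matrix` of RBE-scaled dose.
#' @export
truth_feature_matrix <- function(cohort, organ = c("pc", "larynx"),
                                 flip = FALSE) {
  organ <- match.arg(organ)
  ref <- cohort$reference
  ref_mask <- if (organ == "pc") ref$pc_mask else ref$larynx_mask
  d <- vg_dim(ref_mask)
  idx <- which(ref_mask$values == 1)
  eval_idx <- idx
  if (flip) {
    a <- grid_arrayind(d)[idx, , drop = FALSE]
    eval_idx <- 1L + (d[1] - 1L - a[, 1]) + d[1] * (a[, 2] + d[2] * a[, 3])
  }
  coords <- vg_coords(ref_mask, eval_idx)
  rows <- lapply(cohort$cases, truth_case_row, ref = ref, idx = eval_idx,
                 coords = coords)
  # NB: for flip = TRUE the coords are the mirrored voxel positions, so each
  # row is the left-right mirrored warped dose restricted to the organ
  m <- do.call(rbind, rows)
  ids <- vapply(cohort$cases, function(cs) cs$id, character(1))
  rownames(m) <- ids
  structure(list(values = m, voxel_index = idx, patient_ids = ids,
                 organ = organ, dim = d, spacing = ref_mask$spacing,
                 origin = ref_mask$origin),
            class = "voxel_feature_matrix")
}

#' Regional mean doses and organ-level DVH metrics from feature matrices
#'
#' `features_regional_table()` averages the per-voxel reference-frame dose
#' over the 8 partition subregions; `features_dvh_table()` computes the 7
#' organ-level DVH metrics (means and VxGy) from the same per-voxel doses.
#'
#' @param fm_pc,fm_larynx [truth_feature_matrix()] /
#'   [extract_features()] matrices for the two organs (RBE-scaled dose).
#' @param partition a [partition_subregions()] result.
#' @return numeric matrix, rows = patients.
#' @export
features_regional_table <- function(fm_pc, fm_larynx, partition) {
  lab_pc <- partition$labels[fm_pc$voxel_index]
  lab_l <- partition$labels[fm_larynx$voxel_index]
  agg <- function(m, lab, lv) {
    vapply(lv, function(l) rowMeans(m[, lab == l, drop = FALSE]),
           numeric(nrow(m)))
  }
  out <- cbind(agg(fm_pc$values, lab_pc, 1:6),
               agg(fm_larynx$values, lab_l, 7:8))
  colnames(out) <- partition$levels
  rownames(out) <- fm_pc$patient_ids
  out
}

#' @rdname features_regional_table
#' @export
features_dvh_table <- function(fm_pc, fm_larynx) {
  vx <- function(m, x) 100 * rowMeans(m >= x)
  out <- cbind(pc_mean_dose = rowMeans(fm_pc$values),
               larynx_mean_dose = rowMeans(fm_larynx$values),
               pc_v50 = vx(fm_pc$values, 50),
               pc_v55 = vx(fm_pc$values, 55),
               pc_v60 = vx(fm_pc$values, 60),
               larynx_v50 = vx(fm_larynx$values, 50),
               larynx_v60 = vx(fm_larynx$values, 60))
  rownames(out) <- fm_pc$patient_ids
  out
}
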