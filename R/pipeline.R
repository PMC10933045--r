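#' End-to-end run configuration
#'
#' One config drives the whole pipeline; every stage derives its seeds from
#' the master seed, so a rerun with the same config reproduces all outputs.
#' Numeric defaults follow the study design the pipeline emulates: 80/20
#' split, 5-fold cross-validation, 50 trials, 50 permutation repetitions,
#' classification threshold 0.5.
#'
#' @param seed master seed (required).
#' @param n cohort size.
#' @param shape,spacing reference grid.
#' @param normalization `"register"` (default) or `"truth"`.
#' @param augment_flip left-right flip augmentation for the voxel models.
#' @param n_trials,n_permutations,folds,test_fraction,threshold model
#'   settings.
#' @param max_displacement,field_sigma generator deformation settings, mm.
#' @param planted_subregion truth-model planted label.
#' @param dose_effect truth-model dose effect, log-odds per Gy.
#' @param qc_threshold registration Dice gate.
#' @param out output directory.
#' @return validated config list (class `run_config`).
#' @export
run_config <- function(seed, n = 60, shape = c(64, 64, 80),
                       spacing = c(1.27, 1.27, 1),
                       normalization = "register", augment_flip = TRUE,
                       n_trials = 50, n_permutations = 50, folds = 5,
                       test_fraction = 0.2, threshold = 0.5,
                       max_displacement = 8, field_sigma = 12,
                       planted_subregion = "pc_superior", dose_effect = 0.15,
                       qc_threshold = 0.7, out = tempfile("voxdose_run_")) {
  cfg <- list(seed = seed, n = n, shape = shape, spacing = spacing,
              normalization = normalization, augment_flip = augment_flip,
              n_trials = n_trials, n_permutations = n_permutations,
              folds = folds, test_fraction = test_fraction,
              threshold = threshold, max_displacement = max_displacement,
              field_sigma = field_sigma,
              planted_subregion = planted_subregion,
              dose_effect = dose_effect, qc_threshold = qc_threshold,
              out = out)
  class(cfg) <- "run_config"
  validate_config(cfg)
}

#' Validate (and normalize) a run configuration
#'
#' @param cfg a `run_config` or plain list (e.g. parsed from JSON).
#' @return the validated `run_config`.
#' @export
validate_config <- function(cfg) {
  if (is.null(cfg$seed) || !is.numeric(cfg$seed) || length(cfg$seed) != 1)
    stop("config validation: a single integer `seed` is required")
  defaults <- list(n = 60, shape = c(64, 64, 80), spacing = c(1.27, 1.27, 1),
                   normalization = "register", augment_flip = TRUE,
                   n_trials = 50, n_permutations = 50, folds = 5,
                   test_fraction = 0.2, threshold = 0.5,
                   max_displacement = 8, field_sigma = 12,
                   planted_subregion = "pc_superior", dose_effect = 0.15,
                   qc_threshold = 0.7, out = tempfile("voxdose_run_"))
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  stopifnot(cfg$n >= 10, cfg$folds >= 2, cfg$n_trials >= 1,
            cfg$test_fraction > 0, cfg$test_fraction < 1,
            cfg$normalization %in% c("register", "truth"))
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON file.
#' @return [read_config()]: a validated `run_config`.
#' @export
read_config <- function(path) {
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_config
#' @param cfg a `run_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = 12)
  invisible(path)
}

manifest_checksums <- function(dir) {
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("\\.pdf$|manifest\\.json$|report\\.md$|timings\\.json$", files)]
  sums <- tools::md5sum(files)
  names(sums) <- substring(names(sums), nchar(dir) + 2)
  as.list(sums)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: synthesize the cohort; extract the FT/WL endpoint from
#' the per-patient records; normalize both organs to the reference frame
#' (with Dice QC and optional flip augmentation); compute DVH metrics; fit
#' the per-organ voxel-dose ridge models; run the univariate screen and the
#' clinical-only, DVH-metrics and regional-dose aggregate models with
#' repeated trials, permutation importance and Wilcoxon model comparison.
#' All tables land as CSV, reports as JSON, volumes as NIfTI, plus a
#' manifest with config, seeds and md5 checksums of every artifact.
#'
#' @param config a [run_config()].
#' @return invisibly, the output directory; side effect: the run directory.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage_secs <- new.env(parent = emptyenv())
  stage <- function(name, expr) {
    t0 <- Sys.time()
    on.exit(assign(name, round(as.numeric(Sys.time() - t0), 2),
                   envir = stage_secs), add = TRUE)
    tryCatch(expr, error = function(e) {
      err <- list(stage = name, error = conditionMessage(e))
      jsonlite::write_json(err, file.path(out, "error.json"), auto_unbox = TRUE)
      stop(sprintf("pipeline halted in stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- synth ----------------------------------------------------------------
  cohort <- stage("synth", {
    cc <- cohort_config(shape = config$shape, spacing = config$spacing,
                        max_displacement = config$max_displacement,
                        field_sigma = config$field_sigma,
                        truth = outcome_truth_model(
                          planted_subregion = config$planted_subregion,
                          dose_effect = config$dose_effect))
    co <- generate_cohort(config$n, cc, derive_seed(config$seed, "synth"))
    write_cohort(co, file.path(out, "cohort"))
    co
  })
  clin <- clinical_table(cohort)
  y <- stats::setNames(clin$outcome, clin$id)

  # -- endpoint -------------------------------------------------------------
  stage("endpoint", {
    ep <- do.call(rbind, lapply(cohort$cases, function(cs) {
      e <- extract_endpoint(cs$ft_days, cs$weight_records,
                            cs$rt_start_day, cs$rt_end_day)
      data.frame(id = cs$id, outcome = e$outcome, ft = e$ft, wl = e$wl,
                 eligible = e$eligible)
    }))
    write.csv(ep, file.path(out, "endpoint.csv"), row.names = FALSE)
  })

  # -- register / normalize -------------------------------------------------
  rp <- registration_params(qc_threshold = config$qc_threshold)
  norm_pc <- stage("register_pc",
    normalize_cohort(cohort, "pc", config$normalization, rp,
                     augment_flip = config$augment_flip))
  norm_lar <- stage("register_larynx",
    normalize_cohort(cohort, "larynx", config$normalization, rp,
                     augment_flip = FALSE))
  qc <- rbind(norm_pc$qc, norm_lar$qc)
  write.csv(qc, file.path(out, "qc.csv"), row.names = FALSE)
  keep_ids <- clin$id[clin$id %in% qc$id[qc$pass] |
                        !clin$id %in% qc$id[!qc$pass]]
  excl <- setdiff(clin$id, keep_ids)
  if (length(excl))
    vd_log("excluding %d case(s) failing QC: %s", length(excl),
           paste(excl, collapse = ", "), verbose = TRUE)

  # -- dvh ------------------------------------------------------------------
  dvh_tab <- stage("dvh", {
    m <- dvh_metric_table(cohort)
    write.csv(data.frame(id = rownames(m), m),
              file.path(out, "metrics.csv"), row.names = FALSE)
    m
  })

  # -- voxel models ---------------------------------------------------------
  vox_reports <- list()
  for (organ in c("pc", "larynx")) {
    vox_reports[[organ]] <- stage(paste0("voxel_", organ), {
      nm <- if (organ == "pc") norm_pc else norm_lar
      ref_mask <- if (organ == "pc") cohort$reference$pc_mask
                  else cohort$reference$larynx_mask
      fm <- extract_features(nm$warped_doses[keep_ids], ref_mask, organ)
      fmf <- if (!is.null(nm$flipped_doses))
        extract_features(nm$flipped_doses[keep_ids], ref_mask, organ)
      vm <- fit_voxel_model(fm, y, fm_flipped = fmf,
                            test_fraction = config$test_fraction,
                            folds = config$folds,
                            seed = derive_seed(config$seed, paste0("voxel_", organ)))
      write_nifti(vm$coefficient_map,
                  file.path(out, paste0("coefmap_", organ, ".nii.gz")))
      shares <- importance_summary(vm$coefficient_map, cohort$partition)
      write.csv(data.frame(subregion = names(shares), share = shares),
                file.path(out, paste0("importance_", organ, ".csv")),
                row.names = FALSE)
      jsonlite::write_json(vm$report,
                           file.path(out, paste0("voxel_", organ, ".json")),
                           auto_unbox = TRUE, digits = 10)
      vm$report
    })
  }

  # -- aggregate models -----------------------------------------------------
  agg <- stage("aggregate", {
    covars <- c("treatment_setting", "bilateral", "chemotherapy",
                "dysphagia_grade0", "baseline_weight", "adi", "gender",
                "modality_proton", "smoker", "age")
    uni <- univariate_screen(clin[match(keep_ids, clin$id), ], y[keep_ids],
                             covars)
    write.csv(uni, file.path(out, "univariate.csv"), row.names = FALSE)
    sel <- suppressWarnings(select_covariates(uni))
    if (length(sel) == 0) {
      # degenerate small-cohort screen: fall back to the six smallest
      # p-values so the downstream models remain defined (logged)
      sel <- head(uni$variable[order(uni$p_value)], 6)
      vd_log("univariate screen selected nothing; falling back to top-6 by p",
             verbose = TRUE)
    }
    jsonlite::write_json(sel, file.path(out, "selected_covariates.json"))
    reg_tab <- regional_dose_table(norm_pc, norm_lar, cohort$partition)
    tabs <- build_feature_tables(
      clin[match(keep_ids, clin$id), ],
      dvh_tab[keep_ids, , drop = FALSE],
      reg_tab[keep_ids, , drop = FALSE], sel)
    trials <- list()
    for (mod in names(tabs)) {
      tr <- repeated_trials(tabs[[mod]], y[keep_ids],
                            n_trials = config$n_trials, folds = config$folds,
                            test_fraction = config$test_fraction,
                            seed = derive_seed(config$seed, paste0("trials_", mod)),
                            keep_predictions = TRUE)
      write.csv(data.frame(trial = seq_along(tr$test_auc),
                           test_auc = tr$test_auc, f1 = tr$f1,
                           lambda = tr$lambda),
                file.path(out, paste0("trials_", mod, ".csv")),
                row.names = FALSE)
      write.csv(tr$predictions,
                file.path(out, paste0("predictions_", mod, ".csv")),
                row.names = FALSE)
      trials[[mod]] <- tr
    }
    for (mod in c("dvh", "regional")) {
      pi <- permutation_importance(tabs[[mod]], y[keep_ids],
                                   n_reps = config$n_permutations,
                                   folds = config$folds,
                                   seed = derive_seed(config$seed, paste0("perm_", mod)))
      write.csv(as.data.frame(pi),
                file.path(out, paste0("perm_importance_", mod, ".csv")),
                row.names = FALSE)
    }
    cmp <- list(
      regional_vs_dvh = compare_models(trials$regional$test_auc,
                                       trials$dvh$test_auc),
      regional_vs_clinical = compare_models(trials$regional$test_auc,
                                            trials$clinical$test_auc),
      dvh_vs_clinical = compare_models(trials$dvh$test_auc,
                                       trials$clinical$test_auc))
    jsonlite::write_json(cmp, file.path(out, "comparison.json"),
                         auto_unbox = TRUE, digits = 10)
    list(selected = sel, trials = trials)
  })

  cfg_manifest <- unclass(config)
  cfg_manifest$out <- NULL  # keep manifests path-independent for rerun diffs
  manifest <- list(
    package_version = as.character(utils::packageVersion("voxdose")),
    config = cfg_manifest,
    seeds = list(synth = derive_seed(config$seed, "synth")),
    n_excluded_qc = length(excl),
    checksums = manifest_checksums(out))
  jsonlite::write_json(as.list(stage_secs), file.path(out, "timings.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = 12)
  invisible(out)
}

roc_curve_points <- function(scores, labels, fpr_grid = seq(0, 1, 0.02)) {
  th <- sort(unique(scores), decreasing = TRUE)
  fpr <- c(0, vapply(th, function(t) mean(scores[labels == 0] >= t), numeric(1)), 1)
  tpr <- c(0, vapply(th, function(t) mean(scores[labels == 1] >= t), numeric(1)), 1)
  stats::approx(fpr, tpr, xout = fpr_grid, ties = max, rule = 2)$y
}

#' Summarize a completed run
#'
#' Writes `report.md` (key numbers of every stage, each traceable to a
#' stored CSV/JSON) and, when trial predictions are available, ROC plots
#' with mean +/- sd shading over trials and orthogonal slices of the
#' coefficient maps (PDF). An incomplete run directory yields an error
#' listing the missing artifacts.
#'
#' @param run_dir a [run_pipeline()] output directory.
#' @return invisibly, the path of `report.md`.
#' @export
report <- function(run_dir) {
  required <- c("manifest.json", "qc.csv", "metrics.csv", "univariate.csv",
                "voxel_pc.json", "voxel_larynx.json",
                "trials_clinical.csv", "trials_dvh.csv", "trials_regional.csv",
                "perm_importance_dvh.csv", "perm_importance_regional.csv",
                "comparison.json")
  missing <- required[!file.exists(file.path(run_dir, required))]
  if (length(missing))
    stop("incomplete run; missing artifacts: ", paste(missing, collapse = ", "))
  qc <- read.csv(file.path(run_dir, "qc.csv"))
  uni <- read.csv(file.path(run_dir, "univariate.csv"))
  cmp <- jsonlite::read_json(file.path(run_dir, "comparison.json"),
                             simplifyVector = TRUE)
  lines <- c("# voxdose run report", "",
             "## Registration QC (qc.csv)",
             sprintf("- %s: mean Dice after %.3f (before %.3f), %d/%d pass",
                     unique(qc$organ),
                     vapply(split(qc$dice_after, qc$organ), mean, numeric(1)),
                     vapply(split(qc$dice_before, qc$organ), mean, numeric(1)),
                     vapply(split(qc$pass, qc$organ), sum, numeric(1)),
                     vapply(split(qc$pass, qc$organ), length, numeric(1))),
             "", "## Univariate screen (univariate.csv)",
             sprintf("- %s: OR %.3f [%.3f, %.3f], p = %.3g", uni$variable,
                     uni$or, uni$ci_low, uni$ci_high, uni$p_value),
             "", "## Voxel models (voxel_*.json)")
  for (organ in c("pc", "larynx")) {
    r <- jsonlite::read_json(file.path(run_dir, paste0("voxel_", organ, ".json")),
                             simplifyVector = TRUE)
    lines <- c(lines, sprintf(
      "- %s: train AUC %.3f, test AUC %.3f, CV %.3f +/- %.3f, accuracy %.3f, F1 %.3f",
      organ, r$train_auc, r$test_auc, r$cv_auc_mean, r$cv_auc_sd,
      r$accuracy, r$f1))
  }
  lines <- c(lines, "", "## Aggregate models (trials_*.csv, comparison.json)")
  for (mod in c("clinical", "dvh", "regional")) {
    tr <- read.csv(file.path(run_dir, paste0("trials_", mod, ".csv")))
    note <- if (nrow(tr) > 1) sprintf("%.3f +/- %.3f", mean(tr$test_auc), sd(tr$test_auc))
            else sprintf("%.3f (single trial; no sd)", mean(tr$test_auc))
    lines <- c(lines, sprintf("- %s model: test AUC %s over %d trial(s)",
                              mod, note, nrow(tr)))
  }
  lines <- c(lines,
             sprintf("- regional vs DVH Wilcoxon p = %.3g", cmp$regional_vs_dvh$p_value),
             sprintf("- regional vs clinical p = %.3g; DVH vs clinical p = %.3g",
                     cmp$regional_vs_clinical$p_value, cmp$dvh_vs_clinical$p_value),
             "", "## Permutation importance (perm_importance_*.csv)")
  for (mod in c("dvh", "regional")) {
    pi <- read.csv(file.path(run_dir, paste0("perm_importance_", mod, ".csv")))
    top <- head(pi, 3)
    lines <- c(lines, sprintf("- %s model top features: %s", mod,
                              paste(sprintf("%s (%.4f)", top$feature,
                                            top$mean_auc_loss), collapse = ", ")))
  }
  # ROC plots with mean +/- sd shading over trials
  for (mod in c("dvh", "regional")) {
    pf <- file.path(run_dir, paste0("predictions_", mod, ".csv"))
    if (!file.exists(pf)) next
    pr <- read.csv(pf)
    fpr <- seq(0, 1, 0.02)
    tprs <- vapply(split(pr, pr$trial),
                   function(d) roc_curve_points(d$score, d$label, fpr),
                   numeric(length(fpr)))
    mu <- rowMeans(tprs)
    sdv <- apply(tprs, 1, sd)
    grDevices::pdf(file.path(run_dir, paste0("roc_", mod, ".pdf")), 5, 5)
    plot(fpr, mu, type = "l", xlab = "False positive rate",
         ylab = "True positive rate", main = paste(mod, "model test ROC"))
    if (ncol(tprs) > 1)
      graphics::polygon(c(fpr, rev(fpr)),
                        c(pmin(mu + sdv, 1), rev(pmax(mu - sdv, 0))),
                        border = NA, col = grDevices::rgb(0.2, 0.4, 0.8, 0.25))
    graphics::abline(0, 1, lty = 2)
    grDevices::dev.off()
  }
  for (organ in c("pc", "larynx")) {
    cf <- file.path(run_dir, paste0("coefmap_", organ, ".nii.gz"))
    if (!file.exists(cf)) next
    m <- read_nifti(cf)
    d <- vg_dim(m)
    grDevices::pdf(file.path(run_dir, paste0("coefmap_", organ, ".pdf")), 9, 3)
    graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
    graphics::image(m$values[, , ceiling(d[3] / 2)], main = "axial", axes = FALSE)
    graphics::image(m$values[, ceiling(d[2] / 2), ], main = "coronal", axes = FALSE)
    graphics::image(m$values[ceiling(d[1] / 2), , ], main = "sagittal", axes = FALSE)
    grDevices::dev.off()
  }
  path <- file.path(run_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
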